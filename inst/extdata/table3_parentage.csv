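pedigree_type,n_checked,n_match,pct_printed
cross_two_parents,47,16,34.0
self,14,5,35.7
open_pollination,59,42,71.2
clone,29,17,55.2
total,149,80,53.0
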