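# Small genotype objects built in code for the unit tests.

# build an SSRGenotypes from a list of accession -> list of locus -> c(a, b)
# (NULL cell = untyped); loci taken from the first accession
makeGeno <- function(cells, loci = NULL, meta = NULL) {
    ids <- names(cells)
    if (is.null(loci)) loci <- names(cells[[1L]])
    a1 <- a2 <- matrix(NA_integer_, length(loci), length(ids),
                       dimnames = list(loci, ids))
    for (i in seq_along(ids))
        for (l in loci) {
            g <- cells[[i]][[l]]
            if (!is.null(g)) {
                a1[l, i] <- min(g); a2[l, i] <- max(g)
            }
        }
    SSRGenotypes(a1, a2, meta = meta)
}

# n fully typed accessions at `loci` loci, alleles drawn uniformly from
# `sizes`; deterministic under the caller's seed
randomGeno <- function(n, loci = 12, sizes = seq(100, 130, by = 2)) {
    a1 <- matrix(sample(sizes, loci * n, TRUE), loci, n)
    a2 <- matrix(sample(sizes, loci * n, TRUE), loci, n)
    dimnames(a1) <- dimnames(a2) <-
        list(sprintf("L%02d", 1:loci), sprintf("A%03d", 1:n))
    SSRGenotypes(a1, a2)
}

table1Path <- function()
    system.file("extdata", "table1_diversity.tsv", package = "ssrcurate")
table2Path <- function()
    system.file("extdata", "table2_profiles.tsv", package = "ssrcurate")
table3Path <- function()
    system.file("extdata", "table3_parentage.csv", package = "ssrcurate")

readTable1 <- function()
    read.table(table1Path(), sep = "\t", header = TRUE, check.names = FALSE)

# round half-up, matching the report-table convention
rnd <- function(v, d) floor(v * 10^d + 0.5) / 10^d
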