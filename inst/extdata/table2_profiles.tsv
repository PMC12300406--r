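Sample	BPPCT001	BPPCT007	BPPCT015	BPPCT017	BPPCT038	CPDCT045	CPPCT006	EPPCU5176	UDP-005	UDP-022	UDP-409	UDP-412
AB/6	170, 190	169, 177	- -	157, 161	125, 129	178, **184**	220, 224	205, 205	162, 174	167, 167	158, 168	154, 154
Chui_Huang_Tao	182, 182	177, 177	186, 186	151, 151	131, **149**	176, 176	- -	193, 193	157, 157	165, 169	181, 181	152, 152
Citation	162, **166**	**171**, 177	198, 198	161, 161	123, 131	176, 178	220, 226	**185**, 197	191, 191	165, 165	158, 158	152, 160
Dourado	186, 188	161, 177	180, 180	151, 165	123, 127	176, 178	208, 220	197, 207	**172**, 191	165, 167	158, 158	152, 158
Ferganensis	182, 182	183, 183	- -	161, 161	123, 123	178, 178	220, 220	209, 209	193, **195**	165, 165	183, 183	162, 162
Fiorenza	188, 188	177, 183	198, 198	161, **185**	123, 123	180, 180	220, 220	197, 205	191, 191	165, 171	152, 158	158, 160
Glowin_Star	170, 190	179, 179	198, 198	**134**, 169	123, 123	176, 186	220, 224	207, 207	174, 189	165, 165	160, 183	156, 156
IF_817023	162, 162	- -	186, 186	155, 161	123, 123	167, 180	**216**, 228	191, 191	174, 174	- -	183, 183	**128**, **133**
P1/12	186, 186	177, **198**	198, 198	161, 161	123, 123	176, 176	220, 220	197, 207	176, 176	157, 157	158, 158	156, 158
P5/645	182, 188	161, 177	186, 186	177, 179	135, 135	176, 180	208, 208	**203**, 207	189, 191	165, 171	158, 158	158, 158
Queen_Ruby	176, 184	179, 183	198, 200	161, 161	123, 123	178, 180	208, 220	201, **211**	189, 191	165, 171	158, 158	152, 156
Red_Robin	182, 182	**165**, 175	198, 198	149, 179	129, 135	176, 180	208, 208	197, 201	191, 191	165, 171	152, 158	152, 158
Shan_Dong	184, 184	161, 177	198, 198	149, 179	123, **141**	176, 180	- -	197, 199	174, 191	- -	158, 181	152, 158
XIAGUANG_a	186, 186	**167**, 183	198, 198	159, 161	123, 123	176, 176	208, 208	201, 201	174, 176	171, 171	158, 160	- -
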