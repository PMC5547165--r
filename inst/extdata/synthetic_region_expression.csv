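region,expr_NR3C1,expr_AR
bankssts,6.868393445072283,5.343369492399768
caudalanteriorcingulate,7.006690375958655,4.915093648478982
caudalmiddlefrontal,7.090419575402014,5.457454469813226
cuneus,7.844530410589101,5.945307063775345
entorhinal,8.467590527600724,6.254833512768338
frontalpole,7.8375600259526665,5.7325889719556855
fusiform,6.7822638064824226,5.265908918184129
inferiorparietal,7.043595631762489,5.031940430925533
inferiortemporal,6.495944865511678,4.745711197488692
insula,6.974600149432405,5.335038507369522
isthmuscingulate,6.597060452708629,4.894230247985817
lateraloccipital,7.104818006773017,5.506403318263156
lateralorbitofrontal,7.734062345688065,5.9484018056049175
lingual,8.11550310115036,6.908464763130909
medialorbitofrontal,7.305061009885078,5.628559213770506
middletemporal,6.67172685343336,5.216060301816308
paracentral,7.998102598162841,5.44544152526223
parahippocampal,7.452278233727323,5.063353944729497
parsopercularis,7.444892773082873,5.704126270511651
parsorbitalis,8.676363933847933,5.806215511008723
parstriangularis,8.088615898103342,5.444779689765943
pericalcarine,7.536179884872268,5.477622665924964
postcentral,7.554395834872228,5.301199252876229
posteriorcingulate,6.705175086077959,4.380964540372553
precentral,8.089750871435315,5.739320162333286
precuneus,8.247640965816469,6.426604521710517
rostralanteriorcingulate,6.685796975750432,5.128642802251268
rostralmiddlefrontal,7.570652183642286,5.407384615158303
superiorfrontal,7.541547368466041,5.155088007406902
superiorparietal,7.787013711970484,5.220499903806413
superiortemporal,8.519856668617015,5.989037495842121
supramarginal,8.109315846822028,5.9154206223357795
temporalpole,7.335199710379734,5.308663931913425
transversetemporal,7.7174008709504784,5.9562686730593635
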