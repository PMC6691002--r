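species	transcripts
A_balsamea	46178
L_laricina	50712
P_glauca	37491
P_mariana	58751
P_banksiana	47473
P_strobus	45447
T_occidentalis	38767
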