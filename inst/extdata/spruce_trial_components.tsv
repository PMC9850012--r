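trait	sigma2_F	sigma2_env	h2_published_pct
abh	7.44e-2	1.65	17.31
dbh	3.03e-2	2.15e-1	49.32
rw	5.13e-3	5.63e-2	33.47
wd	2.77e-3	1.95e-2	49.80
trw	5.99e-4	6.04e-3	36.11
ttw	4.73e-4	4.91e-3	35.20
twt	2.47e-3	1.88e-2	46.52
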