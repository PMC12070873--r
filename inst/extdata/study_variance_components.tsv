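component	estimate	se
sigma2_ad	2594.808	86.02
sigma2_as	1007.688	59.78
sigma_ads	206.75063	17.32
sigma2_l	322.848	19.34
sigma2_g	40354.019	260.16
sigma2_e	23234.581	249.36
mean_pen_size	10.9	NA
n_phenotyped	209	NA
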