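combination	T_mya	Ks_avg	Ks_sdv	Ka_avg	Ka_sdv
Claviceps-plants	58.8	1.0612	0.2560	0.2307	0.0064
Claviceps-Epichloe	58.8	0.8517	0.1745	0.1412	0.0073
Triticeae-Poeae	21	0.2767	0.0231	0.1041	0.0008
E.gansuensis-other Epichloe	7.2	0.1435	0.0112	0.0519	0.0055
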