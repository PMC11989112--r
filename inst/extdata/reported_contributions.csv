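model,comparison,client,delta
densenet121,fl_vs_ll,dicle,0.002
densenet121,fl_vs_ll,isbi,0.1251
densenet121,cl_vs_fl,merged,0.0633
densenet121_ca,fl_vs_ll,dicle,0.0313
densenet121_ca,fl_vs_ll,isbi,0.1508
densenet121_ca,cl_vs_fl,merged,0.0023
densenet121_se,fl_vs_ll,dicle,0.0363
densenet121_se,fl_vs_ll,isbi,0.1350
densenet121_se,cl_vs_fl,merged,0.002
densenet121_sa,fl_vs_ll,dicle,0.0242
densenet121_sa,fl_vs_ll,isbi,0.1658
densenet121_sa,cl_vs_fl,merged,-0.0046
densenet121_sa_se,fl_vs_ll,dicle,0.0373
densenet121_sa_se,fl_vs_ll,isbi,0.1522
densenet121_sa_se,cl_vs_fl,merged,-0.0112
densenet121_spp,fl_vs_ll,dicle,0.0205
densenet121_spp,fl_vs_ll,isbi,0.2086
densenet121_spp,cl_vs_fl,merged,0.0257
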