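model,setting,dataset,accuracy
densenet121,cl,merged,0.5000
densenet121_ca,cl,merged,0.7333
densenet121_se,cl,merged,0.7368
densenet121_sa,cl,merged,0.7272
densenet121_sa_se,cl,merged,0.7345
densenet121_spp,cl,merged,0.7244
densenet121,ll,dicle,0.4347
densenet121_ca,ll,dicle,0.6997
densenet121_se,ll,dicle,0.6977
densenet121_sa,ll,dicle,0.7076
densenet121_sa_se,ll,dicle,0.7084
densenet121_spp,ll,dicle,0.6782
densenet121,ll,isbi,0.3116
densenet121_ca,ll,isbi,0.5802
densenet121_se,ll,isbi,0.5990
densenet121_sa,ll,isbi,0.5660
densenet121_sa_se,ll,isbi,0.5935
densenet121_spp,ll,isbi,0.4901
densenet121,fl,merged,0.4367
densenet121_ca,fl,merged,0.7310
densenet121_se,fl,merged,0.7340
densenet121_sa,fl,merged,0.7318
densenet121_sa_se,fl,merged,0.7457
densenet121_spp,fl,merged,0.6987
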