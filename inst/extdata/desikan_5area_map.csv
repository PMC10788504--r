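region,area
lh_bankssts,temporal
lh_caudalanteriorcingulate,executive
lh_caudalmiddlefrontal,pre/motor
lh_cuneus,occipital
lh_entorhinal,temporal
lh_frontalpole,executive
lh_fusiform,temporal
lh_inferiorparietal,parietal
lh_inferiortemporal,temporal
lh_insula,executive
lh_isthmuscingulate,parietal
lh_lateraloccipital,occipital
lh_lateralorbitofrontal,executive
lh_lingual,occipital
lh_medialorbitofrontal,executive
lh_middletemporal,temporal
lh_paracentral,pre/motor
lh_parahippocampal,temporal
lh_parsopercularis,executive
lh_parsorbitalis,executive
lh_parstriangularis,executive
lh_pericalcarine,occipital
lh_postcentral,parietal
lh_posteriorcingulate,parietal
lh_precentral,pre/motor
lh_precuneus,parietal
lh_rostralanteriorcingulate,executive
lh_rostralmiddlefrontal,executive
lh_superiorfrontal,pre/motor
lh_superiorparietal,parietal
lh_superiortemporal,temporal
lh_supramarginal,parietal
lh_temporalpole,temporal
lh_transversetemporal,temporal
rh_bankssts,temporal
rh_caudalanteriorcingulate,executive
rh_caudalmiddlefrontal,pre/motor
rh_cuneus,occipital
rh_entorhinal,temporal
rh_frontalpole,executive
rh_fusiform,temporal
rh_inferiorparietal,parietal
rh_inferiortemporal,temporal
rh_insula,executive
rh_isthmuscingulate,parietal
rh_lateraloccipital,occipital
rh_lateralorbitofrontal,executive
rh_lingual,occipital
rh_medialorbitofrontal,executive
rh_middletemporal,temporal
rh_paracentral,pre/motor
rh_parahippocampal,temporal
rh_parsopercularis,executive
rh_parsorbitalis,executive
rh_parstriangularis,executive
rh_pericalcarine,occipital
rh_postcentral,parietal
rh_posteriorcingulate,parietal
rh_precentral,pre/motor
rh_precuneus,parietal
rh_rostralanteriorcingulate,executive
rh_rostralmiddlefrontal,executive
rh_superiorfrontal,pre/motor
rh_superiorparietal,parietal
rh_superiortemporal,temporal
rh_supramarginal,parietal
rh_temporalpole,temporal
rh_transversetemporal,temporal
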