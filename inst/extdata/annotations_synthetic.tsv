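gene_symbol	category
Igf1r	aging/longevity
Foxo3	aging/longevity
Sirt6	aging/longevity
Pim1	transcription factor
Cbx3	transcription factor
Cux1	transcription factor
Sod1	oxidative stress
Mt3	oxidative stress
Gsk3b	autophagy
Fbxw7	autophagy
Pikfyve	autophagy
Mgmt	DNA damage/repair
Rad9b	DNA damage/repair
Otub1	DNA damage/repair
Slc26a5	ion channel
Kcnq4	ion channel
Slc7a14	ion channel
Myo7a	stereocilia
Tmem63b	ion channel
Dnm1	synapse
Dnm3	synapse
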