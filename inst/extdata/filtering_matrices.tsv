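sample_id	reads_produced	high_quality_reads	retained_after_host_filter
Vaginal-NT	154701	151193	4266
Vaginal-T	222202	211864	159017
Gastric antrum-NT	101522	99529	494
Gastric antrum-T	59749	56936	251
Gastric body-NT	136117	133250	1214
Gastric body-T	143220	139737	199
Saliva-NT	134011	131338	30156
Saliva-T	225114	218562	208893
Skin-NT	242037	233438	128078
Skin-T	236997	227914	163985
Sputum-NT	77837	52182	9776
Sputum-T	208337	203745	200275
Nasopharyngeal-Swab-NT	78150	71634	3613
Nasopharyngeal-Swab-T	4184	4017	3933
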