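sample_id	reads_produced	high_quality_reads	retained_after_host_filter
Sputum-0.0125%	51453	48877	31094
Sputum-0.05%	34712	33795	31860
Sputum-0.1%	41873	40807	39754
Sputum-0.5%	13420	13056	12774
Sputum-1.5%	34688	33633	32716
Sputum-2%	37528	36418	35249
Sputum-NT	38545	37556	17595
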