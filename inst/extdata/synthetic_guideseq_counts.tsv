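nuclease	site_id	is_on_target	unique_reads
SpCas9WT	on_target	TRUE	1000
SpCas9WT	OT1	FALSE	220
SpCas9WT	OT2	FALSE	180
SpCas9WT	OT3	FALSE	100
SpCas9-SaCas9	on_target	TRUE	900
SpCas9-SaCas9	OT1	FALSE	40
SpCas9-SaCas9	OT2	FALSE	20
SpCas9-NmCas9	on_target	TRUE	850
SpCas9-NmCas9	OT1	FALSE	10
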