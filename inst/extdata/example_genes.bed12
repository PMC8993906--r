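chr1	151000	172500	TSG1|T1	0	+	151000	172500	0	2	600,900	0,20600
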