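id	parent	start	end	partner	outcome	note
QQS-1-12	QQS	1	12	AtNF-YC4	binds	MBP pull-down; reciprocal GST-bait assay failed, attributed to masking by the GST moiety
QQS-11-59	QQS	11	59	AtNF-YC4	binds	MBP pull-down
QQS-13-47	QQS	13	47	AtNF-YC4	no_binding	MBP pull-down
QQS-41-59	QQS	41	59	AtNF-YC4	binds	MBP pull-down
QQS-48-59	QQS	48	59	AtNF-YC4	no_binding	MBP pull-down
QQS-1-12	QQS	1	12	HsNF-YC-1-145	binds	MBP pull-down; reciprocal GST-bait assay failed, attributed to masking by the GST moiety
QQS-11-59	QQS	11	59	HsNF-YC-1-145	binds	MBP pull-down
QQS-13-47	QQS	13	47	HsNF-YC-1-145	not_tested	untested against this partner
QQS-41-59	QQS	41	59	HsNF-YC-1-145	binds	MBP pull-down
QQS-48-59	QQS	48	59	HsNF-YC-1-145	not_tested	untested against this partner
HsNF-YC-1-145	HsNF-YC	1	145	QQS-11-59	binds	GST pull-down with QQS fragment as bait
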