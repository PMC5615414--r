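name	kind	synonyms
Dyslipidemia	disease	Dyslipidemia|Dyslipidaemia
Hyperlipidemia	disease	Hyperlipidemia|Hyperlipidaemia
Hypercholesterolemia	disease	Hypercholesterolemia|Hypercholesterolaemia
Hypertriglyceridemia	disease	Hypertriglyceridemia|Hypertriglyceridaemia
HDL-Cholesterol	identifier	HDL-Cholesterol|HDL cholesterol|HDL-C
HDL	identifier	HDL|high-density lipoprotein
LDL-Cholesterol	identifier	LDL-Cholesterol|LDL cholesterol|LDL-C
LDL	identifier	LDL|low-density lipoprotein
Triglyceride	identifier	Triglyceride|Triglycerides|TG
Low HDL-C	identifier	Low HDL-C
High LDL-C	identifier	High LDL-C
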