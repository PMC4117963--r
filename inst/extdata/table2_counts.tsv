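breed	tissue	methylated_cgis	total_cgis
TH	muscle	13467	109505
TH	heart	8377	109505
TH	lung	14056	109505
TH	cerebrum	11082	109505
JH	muscle	12345	109505
JH	heart	11232	109505
JH	lung	13939	109505
JH	cerebrum	8560	109505
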