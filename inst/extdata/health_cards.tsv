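ON_grouped	\b\d{4}[- ]\d{3}[- ]\d{3}([- ]?[A-Z]{2})?\b
ON_plain	\b\d{10}( ?[A-Z]{2})?\b
QC	\b[A-Z]{4} ?\d{4} ?\d{4}\b
BC	\b9\d{9}\b
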