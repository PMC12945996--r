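"drug","n_reports","total_published"
"Avatrombopag",105,2092
"Eltrombopag",1044,2092
"Romiplostim",943,2092
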