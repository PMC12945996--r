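"group","n","percent_published"
"0-30 days",282,30.92
"31-60 days",149,16.34
"61-90 days",93,10.2
"91-120 days",67,7.34
"121-150 days",40,4.39
"151-180 days",37,4.06
"181-360 days",104,11.4
">360 days",140,15.35
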