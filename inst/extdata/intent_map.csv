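prefix,intent
W32,unintentional
W33,unintentional
W34,unintentional
X72,self-inflicted
X73,self-inflicted
X74,self-inflicted
X93,assault
X94,assault
X95,assault
Y22,undetermined
Y23,undetermined
Y24,undetermined
Y35.0,legal intervention
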