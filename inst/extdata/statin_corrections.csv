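"statin","dose","reduction"
"atorvastatin",10,0.37
"atorvastatin",20,0.43
"atorvastatin",40,0.49
"atorvastatin",80,0.55
"rosuvastatin",5,0.38
"rosuvastatin",10,0.43
"rosuvastatin",20,0.48
"rosuvastatin",40,0.53
"simvastatin",10,0.27
"simvastatin",20,0.32
"simvastatin",40,0.37
"simvastatin",80,0.42
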