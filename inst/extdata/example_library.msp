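Name: alanine-2TMS
Area: 48210
Num Peaks: 6
116 999 73 842 147 510 190 215 86 130 218 55

Name: glycine-3TMS
Area: 35120
Num Peaks: 5
174 999 86 617 73 580 248 204 100 98

Name: serine-3TMS
Area: 29876
Num Peaks: 6
204 999 73 740 218 430 100 212 306 120 147 95

Name: succinic acid-2TMS
Area: 18440
Num Peaks: 5
147 999 73 690 247 402 129 161 172 77

Name: citric acid-4TMS
Area: 15932
Num Peaks: 6
273 999 147 740 73 651 347 280 183 120 375 64

Name: palmitic acid-TMS
Area: 22305
Num Peaks: 5
117 999 73 560 313 420 145 180 328 95
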