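Name: peak_0413
Area: 45102
Num Peaks: 6
116:965; 73:870; 147:489; 190:230; 86:118; 218:61;

Name: peak_0413
Area: 9315
Num Peaks: 4
116:310; 73:295; 147:144; 190:70;

Name: peak_0522
Area: 31240
Num Peaks: 5
174:980; 86:633; 73:560; 248:195; 100:104;

Name: peak_0671
Area: 27018
Num Peaks: 6
204:971; 73:725; 218:448; 100:205; 306:131; 147:88;

Name: peak_0790
Area: 16881
Num Peaks: 5
147:940; 73:712; 247:385; 129:150; 172:84;

Name: peak_0944
Area: 20100
Num Peaks: 5
117:958; 73:540; 313:441; 145:167; 328:102;
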