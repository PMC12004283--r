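id,group,excluded,reason
H01,HC,0,
H02,HC,0,
H03,HC,1,ecg-recording-loss
H04,HC,0,
H05,HC,0,
H06,HC,0,
H07,HC,0,
H08,HC,0,
H09,HC,0,
H10,HC,0,
H11,HC,1,ecg-recording-loss
H12,HC,0,
H13,HC,0,
H14,HC,0,
H15,HC,0,
H16,HC,0,
H17,HC,0,
H18,HC,0,
H19,HC,0,
D01,DOC,0,
D02,DOC,0,
D03,DOC,0,
D04,DOC,0,
D05,DOC,0,
D06,DOC,0,
D07,DOC,0,
D08,DOC,0,
D09,DOC,0,
D10,DOC,0,
D11,DOC,0,
D12,DOC,1,electrode-detachment-or-noise
D13,DOC,1,electrode-detachment-or-noise
D14,DOC,1,electrode-detachment-or-noise
D15,DOC,1,electrode-detachment-or-noise
D16,DOC,1,electrode-detachment-or-noise
D17,DOC,1,electrode-detachment-or-noise
D18,DOC,1,electrode-detachment-or-noise
D19,DOC,1,electrode-detachment-or-noise
D20,DOC,1,electrode-detachment-or-noise
D21,DOC,1,electrode-detachment-or-noise
D22,DOC,1,electrode-detachment-or-noise
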