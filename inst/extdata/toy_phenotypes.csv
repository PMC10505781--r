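animal,age,value,herd_year,birth_month
F1,20,99.1,1,1
F2,20,99.2,1,1
F3,20,99.3,1,1
F4,20,99.4,1,1
F5,20,99.5,1,1
F6,20,99.6,1,1
F7,20,99.7,1,1
F8,20,99.8,1,1
F9,20,99.9,1,1
F10,20,100,1,1
F11,20,100.1,1,1
F12,20,100.2,1,1
F13,20,100.3,1,1
F14,20,100.4,1,1
F15,20,100.5,1,1
F16,20,100.6,1,1
F17,20,100.7,1,1
F18,20,100.8,1,1
F19,20,100.9,1,1
F20,20,101,1,1
F21,20,101.1,1,1
F22,20,101.2,1,1
F23,20,101.3,1,1
F24,20,101.4,1,1
F25,20,101.5,1,1
F26,20,101.6,1,1
F27,20,101.7,1,1
F28,20,101.8,1,1
F29,20,101.9,1,1
F30,20,102,1,1
A1,5,101,1,1
A1,20,100,1,1
A1,40,120,1,1
A2,12,102,1,1
A2,20,100.3,1,1
A2,40,121,1,1
A3,5,100.5,1,1
A3,20,99.8,1,1
A4,5,100.8,1,1
A4,20,200,1,1
A4,40,119.5,1,1
A5,5,100.2,1,1
A5,8,103,1,1
A5,25,111,1,1
A6,5,99.5,1,1
A6,20,100.1,1,1
A6,40,118,1,1
A6,50,125,1,1
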