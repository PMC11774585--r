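element,isotope,group,replicate,concentration_ugL,below_lod
B,,sample,S1,1.5591,FALSE
B,,sample,S2,1.8304,FALSE
B,,sample,S3,1.4958,FALSE
B,,sample,S4,2.4208,FALSE
B,,control,C1,0.4187,FALSE
B,,control,C2,0.3334,FALSE
B,,control,C3,0.432,FALSE
B,,control,C4,0.454,FALSE
Mn,,sample,S1,1.3188,FALSE
Mn,,sample,S2,1.1076,FALSE
Mn,,sample,S3,1.5874,FALSE
Mn,,sample,S4,1.2711,FALSE
Mn,,control,C1,0.4335,FALSE
Mn,,control,C2,0.3162,FALSE
Mn,,control,C3,0.6126,FALSE
Mn,,control,C4,0.4859,FALSE
Fe,,sample,S1,3.1278,FALSE
Fe,,sample,S2,3.7828,FALSE
Fe,,sample,S3,3.692,FALSE
Fe,,sample,S4,3.5295,FALSE
Fe,,control,C1,2.3526,FALSE
Fe,,control,C2,2.2897,FALSE
Fe,,control,C3,1.9903,FALSE
Fe,,control,C4,1.3225,FALSE
Zn,,sample,S1,2.6608,FALSE
Zn,,sample,S2,2.3274,FALSE
Zn,,sample,S3,2.2819,FALSE
Zn,,sample,S4,1.7587,FALSE
Zn,,control,C1,1.338,FALSE
Zn,,control,C2,1.5978,FALSE
Zn,,control,C3,1.925,FALSE
Zn,,control,C4,1.4412,FALSE
Co,,sample,S1,0.2965,FALSE
Co,,sample,S2,0.2717,FALSE
Co,,sample,S3,0.209,FALSE
Co,,sample,S4,0.2529,FALSE
Co,,control,C1,0.1814,FALSE
Co,,control,C2,0.1938,FALSE
Co,,control,C3,0.2439,FALSE
Co,,control,C4,0.2281,FALSE
Cu,,sample,S1,0.7973,FALSE
Cu,,sample,S2,0.7834,FALSE
Cu,,sample,S3,0.9456,FALSE
Cu,,sample,S4,0.9197,FALSE
Cu,,control,C1,0.5133,FALSE
Cu,,control,C2,0.5114,FALSE
Cu,,control,C3,0.6324,FALSE
Cu,,control,C4,0.6851,FALSE
Ni,,sample,S1,0.537,FALSE
Ni,,sample,S2,0.6538,FALSE
Ni,,sample,S3,0.5942,FALSE
Ni,,sample,S4,0.4864,FALSE
Ni,,control,C1,0.4196,FALSE
Ni,,control,C2,0.3136,FALSE
Ni,,control,C3,0.5209,FALSE
Ni,,control,C4,0.5806,FALSE
W,,sample,S1,0.2371,FALSE
W,,sample,S2,0.2073,FALSE
W,,sample,S3,0.2854,FALSE
W,,sample,S4,0.2482,FALSE
W,,control,C1,0.3156,FALSE
W,,control,C2,0.1946,FALSE
W,,control,C3,0.2248,FALSE
W,,control,C4,0.1972,FALSE
Al,,sample,S1,,TRUE
Al,,sample,S2,,TRUE
Al,,sample,S3,,TRUE
Al,,sample,S4,,TRUE
Al,,control,C1,,TRUE
Al,,control,C2,,TRUE
Al,,control,C3,,TRUE
Al,,control,C4,,TRUE
Se,,sample,S1,,TRUE
Se,,sample,S2,,TRUE
Se,,sample,S3,,TRUE
Se,,sample,S4,,TRUE
Se,,control,C1,,TRUE
Se,,control,C2,,TRUE
Se,,control,C3,,TRUE
Se,,control,C4,,TRUE
Mo,,sample,S1,,TRUE
Mo,,sample,S2,,TRUE
Mo,,sample,S3,,TRUE
Mo,,sample,S4,,TRUE
Mo,,control,C1,,TRUE
Mo,,control,C2,,TRUE
Mo,,control,C3,,TRUE
Mo,,control,C4,,TRUE
Li,,sample,S1,0.3798,FALSE
Li,,sample,S2,0.3722,FALSE
Li,,sample,S3,0.317,FALSE
Li,,sample,S4,0.4484,FALSE
Li,,control,C1,0.3702,FALSE
Li,,control,C2,0.3379,FALSE
Li,,control,C3,0.4028,FALSE
Li,,control,C4,0.3286,FALSE
V,,sample,S1,0.1828,FALSE
V,,sample,S2,0.2101,FALSE
V,,sample,S3,0.1847,FALSE
V,,sample,S4,0.2143,FALSE
V,,control,C1,0.1734,FALSE
V,,control,C2,0.1978,FALSE
V,,control,C3,0.1637,FALSE
V,,control,C4,0.2024,FALSE
Cr,,sample,S1,0.5168,FALSE
Cr,,sample,S2,0.8349,FALSE
Cr,,sample,S3,0.6781,FALSE
Cr,,sample,S4,0.7046,FALSE
Cr,,control,C1,0.529,FALSE
Cr,,control,C2,0.6841,FALSE
Cr,,control,C3,0.4323,FALSE
Cr,,control,C4,0.4475,FALSE
As,,sample,S1,0.3125,FALSE
As,,sample,S2,0.2069,FALSE
As,,sample,S3,0.2259,FALSE
As,,sample,S4,0.2177,FALSE
As,,control,C1,0.1841,FALSE
As,,control,C2,0.1856,FALSE
As,,control,C3,0.2163,FALSE
As,,control,C4,0.1893,FALSE
Sr,,sample,S1,1.0645,FALSE
Sr,,sample,S2,1.5352,FALSE
Sr,,sample,S3,1.1277,FALSE
Sr,,sample,S4,1.1356,FALSE
Sr,,control,C1,0.9613,FALSE
Sr,,control,C2,1.1292,FALSE
Sr,,control,C3,0.9664,FALSE
Sr,,control,C4,0.9733,FALSE
Cd,,sample,S1,0.1028,FALSE
Cd,,sample,S2,0.1104,FALSE
Cd,,sample,S3,0.1191,FALSE
Cd,,sample,S4,0.1047,FALSE
Cd,,control,C1,0.1089,FALSE
Cd,,control,C2,0.0726,FALSE
Cd,,control,C3,0.1042,FALSE
Cd,,control,C4,0.0723,FALSE
Pt,,sample,S1,0.1109,FALSE
Pt,,sample,S2,0.106,FALSE
Pt,,sample,S3,0.1034,FALSE
Pt,,sample,S4,0.1164,FALSE
Pt,,control,C1,0.0671,FALSE
Pt,,control,C2,0.1238,FALSE
Pt,,control,C3,0.0705,FALSE
Pt,,control,C4,0.0895,FALSE
Pb,206,sample,S1,0.3538,FALSE
Pb,206,sample,S2,0.3803,FALSE
Pb,206,sample,S3,0.6671,FALSE
Pb,206,sample,S4,0.4428,FALSE
Pb,206,control,C1,0.228,FALSE
Pb,206,control,C2,0.2126,FALSE
Pb,206,control,C3,0.3216,FALSE
Pb,206,control,C4,0.2931,FALSE
Pb,207,sample,S1,0.4143,FALSE
Pb,207,sample,S2,0.3671,FALSE
Pb,207,sample,S3,0.3287,FALSE
Pb,207,sample,S4,0.3566,FALSE
Pb,207,control,C1,0.3586,FALSE
Pb,207,control,C2,0.2601,FALSE
Pb,207,control,C3,0.2236,FALSE
Pb,207,control,C4,0.426,FALSE
Pb,208,sample,S1,0.48,FALSE
Pb,208,sample,S2,0.4209,FALSE
Pb,208,sample,S3,0.5442,FALSE
Pb,208,sample,S4,0.5259,FALSE
Pb,208,control,C1,0.2602,FALSE
Pb,208,control,C2,0.4554,FALSE
Pb,208,control,C3,0.2797,FALSE
Pb,208,control,C4,0.2219,FALSE
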