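label	modality	x	y	z	roi
Fp1	eeg	-17	85	49	L-FP
Fpz	eeg	0	85	50	L-FP
Fp2	eeg	17	85	49	R-FP
AF7	eeg	-68	68	38	L-dlPFC
AF3	eeg	-26	64	23	L-dlPFC
AFz	eeg	2	64	27	R-FP
AF4	eeg	31	61	26	R-FP
AF8	eeg	68	68	38	R-dlPFC
F7	eeg	-68	50	45	other
F5	eeg	-51	50	53	L-dlPFC
F3	eeg	-34	50	58	L-dlPFC
F1	eeg	-17	50	61	other
Fz	eeg	0	50	62	other
F2	eeg	17	50	61	other
F4	eeg	34	50	58	R-dlPFC
F6	eeg	51	50	53	R-dlPFC
F8	eeg	68	50	45	other
FT7	eeg	-68	28	50	other
FC5	eeg	-51	28	57	other
FC3	eeg	-34	28	62	other
FC1	eeg	-17	28	65	other
FCz	eeg	0	28	66	other
FC2	eeg	17	28	65	other
FC4	eeg	50	13	51	R-dlPFC
FC6	eeg	51	28	57	other
FT8	eeg	68	28	50	other
T7	eeg	-68	0	52	other
C5	eeg	-51	0	59	other
C3	eeg	-34	0	64	other
C1	eeg	-17	0	67	other
Cz	eeg	0	0	68	other
C2	eeg	17	0	67	other
C4	eeg	34	0	64	other
C6	eeg	51	0	59	other
T8	eeg	68	0	52	other
TP7	eeg	-68	-28	50	other
CP5	eeg	-51	-28	57	other
CP3	eeg	-34	-28	62	other
CP1	eeg	-17	-28	65	other
CPz	eeg	0	-28	66	other
CP2	eeg	17	-28	65	other
CP4	eeg	34	-28	62	other
CP6	eeg	51	-28	57	other
TP8	eeg	68	-28	50	other
P9	eeg	-85	-55	30	other
P7	eeg	-68	-55	43	other
P5	eeg	-51	-55	52	other
P3	eeg	-34	-55	57	other
P1	eeg	-17	-55	60	other
Pz	eeg	0	-55	61	other
P2	eeg	17	-55	60	other
P4	eeg	34	-55	57	other
P6	eeg	51	-55	52	other
P8	eeg	68	-55	43	other
P10	eeg	85	-55	30	other
PO7	eeg	-68	-75	35	other
PO3	eeg	-34	-75	50	other
POz	eeg	0	-75	55	other
PO4	eeg	34	-75	50	other
PO8	eeg	68	-75	35	other
O1	eeg	-17	-90	47	other
Oz	eeg	0	-90	48	other
O2	eeg	17	-90	47	other
Iz	eeg	0	-105	39	other
HEOG	eog	-40	85	-30	other
VEOG	eog	0	95	-20	other
ch1	fnirs	-52	55	22	L-dlPFC
ch2	fnirs	-44	57	23	L-dlPFC
ch3	fnirs	-36	59	25	L-dlPFC
ch4	fnirs	-26	62	27	L-FP
ch5	fnirs	-16	64	29	L-FP
ch6	fnirs	-6	66	31	L-FP
ch7	fnirs	4	67	31	L-FP
ch8	fnirs	6	66	31	R-FP
ch9	fnirs	16	64	29	R-FP
ch10	fnirs	26	62	27	R-FP
ch11	fnirs	36	59	25	R-FP
ch12	fnirs	38	58	24	R-dlPFC
ch13	fnirs	46	56	23	R-dlPFC
ch14	fnirs	54	54	21	R-dlPFC
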