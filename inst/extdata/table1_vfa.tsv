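cow	time	timepoint	formic	acetic	propionic	iso_butyric	butyric	iso_valeric	valeric	caproic	heptanoic	lactic	succinic	total	ph
1	04:00	NA	0.0	63.4	16.8	0.8	16.2	0.5	1.8	0.2	0.0	0.0	0.0	99.7	NA
1	07:00	t0	0.0	62.4	15.4	0.9	14.9	0.6	1.6	0.2	0.0	0.0	0.0	95.9	6.67
1	08:00	t1	0.0	61.6	19.6	0.8	15.2	0.6	1.5	0.2	0.0	9.1	0.1	108.8	6.22
1	10:00	t3	0.0	67.2	20.7	1.0	16.7	0.6	2.2	0.2	0.0	0.3	0.0	108.8	6.22
1	12:00	t5	0.0	54.3	13.4	0.8	11.9	0.4	1.3	0.1	0.0	0.0	0.0	82.1	6.56
1	14:00	NA	0.0	55.9	13.0	0.8	11.0	0.4	1.0	0.1	0.0	1.5	0.0	83.8	NA
1	16:00	NA	0.0	59.3	22.6	0.8	15.9	0.7	1.7	0.2	0.0	0.9	0.0	102.1	NA
2	04:00	NA	0.0	49.7	23.3	0.8	7.3	0.4	3.0	0.5	0.1	0.0	0.0	85.1	NA
2	07:00	t0	0.0	56.7	24.4	0.9	7.3	0.4	2.7	0.5	0.1	0.0	0.0	93.1	6.68
2	08:00	t1	0.0	55.7	21.6	0.9	11.4	0.5	4.2	1.0	0.1	0.9	0.0	96.2	6.48
2	10:00	t3	0.0	66.1	30.6	1.0	12.8	0.6	4.9	1.2	0.2	0.0	0.0	117.3	6.22
2	12:00	t5	0.0	60.1	27.7	1.0	9.3	0.5	3.4	0.8	0.1	0.0	0.0	102.8	6.54
2	14:00	NA	0.0	59.7	24.4	0.9	8.6	0.5	2.9	0.6	0.1	6.8	0.2	104.7	NA
2	16:00	NA	0.3	54.2	23.0	0.7	15.3	0.5	4.9	1.4	0.1	16.2	0.2	116.7	NA
3	04:00	NA	0.0	59.9	24.8	0.7	10.6	0.4	2.1	0.5	0.1	0.0	0.0	99.0	NA
3	07:00	t0	0.0	54.7	18.7	0.8	8.6	0.3	1.3	0.3	0.0	0.0	0.0	84.8	6.84
3	08:00	t1	0.0	59.4	21.8	0.9	12.0	0.5	2.0	0.6	0.0	0.0	0.0	97.2	6.46
3	10:00	t3	0.0	61.3	23.0	0.8	11.1	0.4	1.7	0.5	0.0	0.0	0.0	98.9	6.47
3	12:00	t5	0.0	60.3	21.1	0.9	10.0	0.5	1.4	0.4	0.0	0.0	0.0	94.6	6.76
3	14:00	NA	0.0	62.6	20.9	0.9	11.3	0.5	1.3	0.4	0.0	8.3	0.1	106.2	NA
3	16:00	NA	0.0	65.5	29.1	1.0	17.6	0.8	2.4	0.8	0.0	1.7	0.0	118.9	NA
4	04:00	NA	0.0	70.2	32.3	0.8	12.4	0.5	3.2	0.4	0.0	0.0	0.0	119.9	NA
4	07:00	t0	0.0	56.1	21.4	0.7	8.0	0.3	1.7	0.2	0.0	0.0	0.0	88.4	6.52
4	08:00	t1	0.0	54.2	18.9	0.8	8.1	0.3	1.5	0.2	0.0	0.0	0.1	84.0	6.71
4	10:00	t3	0.0	60.8	20.0	0.9	7.8	0.4	1.3	0.2	0.0	0.0	0.0	91.4	6.71
4	12:00	t5	0.0	53.0	15.8	0.9	6.1	0.4	0.8	0.1	0.0	0.0	0.0	77.0	6.91
4	14:00	NA	0.0	53.5	15.5	0.9	8.7	0.4	1.2	0.2	0.0	4.9	0.0	85.2	NA
4	16:00	NA	0.0	64.5	24.8	0.9	21.6	0.7	3.5	0.6	0.0	10.7	0.0	127.3	NA
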