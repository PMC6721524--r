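arm	length_mb
1p	125.0
1q	124.3
2p	93.3
2q	149.9
3p	91.0
3q	107.0
4p	50.4
4q	140.8
5p	48.4
5q	132.5
6p	61.0
6q	110.1
7p	59.9
7q	99.2
8p	45.6
8q	100.8
9p	49.0
9q	92.2
10p	40.2
10q	95.3
11p	53.7
11q	81.3
12p	35.8
12q	98.1
13q	97.3
14q	89.7
15q	83.5
16p	36.6
16q	53.8
17p	24.0
17q	57.2
18p	17.2
18q	60.9
19p	26.5
19q	32.6
20p	27.5
20q	35.5
21q	34.9
22q	36.6
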