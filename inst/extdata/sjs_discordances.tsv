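gene	true_type	true_n	method	called_type	count
A	A*02:01	33	v1	A*02:06	2
A	A*26:02	3	v1	A*26:01	1
A	A*31:01	18	v1	A*33:03	1
A	A*02:01	33	v2	A*02:06	1
A	A*24:02	55	v2	fail	1
B	B*15:01	8	v1	B*46:01	1
B	B*40:06	8	v1	B*40:02	5
B	B*51:01	21	v1	B*51:02	4
B	B*54:01	8	v1	B*55:01	1
B	B*55:02	4	v1	B*55:01	2
B	B*56:01	3	v1	B*55:01	3
B	B*59:04	1	v1	B*59:01	1
B	B*15:27	1	v2	B*15:01	1
B	B*51:01	21	v2	B*51:02	3
B	B*59:04	1	v2	B*59:01	1
C	C*01:02	40	v1	C*14:02	1
C	C*04:82	1	v1	C*04:01	1
C	C*14:03	28	v1	C*14:02	20
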