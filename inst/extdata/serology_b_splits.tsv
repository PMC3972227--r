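allele	category
B*14:01	B*14(64)
B*14:02	B*14(65)
B*14:03	B*14(65)
B*15:01	B*15(62)
B*15:02	B*15(75)
B*15:03	B*15(72)
B*15:04	B*15(62)
B*15:05	B*15(62)
B*15:06	B*15(62)
B*15:07	B*15(62)
B*15:08	B*15(75)
B*15:09	B*15(70)
B*15:10	B*15(71)
B*15:11	B*15(75)
B*15:12	B*15(76)
B*15:13	B*15(77)
B*15:14	B*15(76)
B*15:15	B*15(62)
B*15:16	B*15(63)
B*15:17	B*15(63)
B*15:18	B*15(71)
B*15:20	B*15(62)
B*15:21	B*15(75)
B*15:24	B*15(62)
B*15:25	B*15(62)
B*15:27	B*15(62)
B*15:28	B*15(62)
B*15:30	B*15(75)
B*15:31	B*15(75)
B*15:32	B*15(75)
B*15:34	B*15(62)
B*15:35	B*15(62)
B*15:37	B*15
B*15:58	B*15
B*40:01	B*40(60)
B*40:02	B*40(61)
B*40:03	B*40(61)
B*40:04	B*40(61)
B*40:05	B*40(40)
B*40:06	B*40(61)
B*40:07	B*40
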