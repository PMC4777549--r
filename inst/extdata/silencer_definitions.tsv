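family	consensus_length	delta7_start	delta7_end	delta8_start	delta8_end	note
Mos1	1289	681	1212	903	1212	exact; prose also calls Delta8 'the last 317 bp' while 903-1212 spans 310 bp (discrepancy recorded, 903-1212 retained)
Hsmar1	1287	679	1210	901	1210	approximate (Mos1-aligned positions); edit to your own consensus alignment
Hsmar2	1300	692	1223	914	1223	approximate (Mos1-aligned positions); edit to your own consensus alignment
Himar1	1287	679	1210	901	1210	approximate (Mos1-aligned positions); edit to your own consensus alignment
Mcmar1	1284	676	1207	898	1207	approximate (Mos1-aligned positions); edit to your own consensus alignment
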