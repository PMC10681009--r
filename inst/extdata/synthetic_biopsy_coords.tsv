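sample_id	x	y
S01	0.537725721275237	-0.740130791928503
S02	0.166046317780362	-0.541568234835616
S03	-0.216689301055427	0.795870011373854
S04	-0.625909541951055	-0.553543466590427
S05	0.270753597690358	-0.619436602281147
S06	0.837503754124174	0.00278712325100321
S07	0.639084225694582	0.0853366629600167
S08	-0.513399505476326	0.199073040954684
S09	-0.234489539364481	0.906423039329931
S10	0.154316911710813	0.308600912138477
S11	0.936421763305958	-0.158104813351168
S12	-0.442328845453661	-0.870317830045415
S13	-0.352576197492493	-0.761080211469884
S14	0.67705069273122	0.239557590481843
S15	0.655282221321364	-0.141639212570075
S16	0.908868113897832	0.12724178190203
S17	-0.19963930903744	-0.265434034659973
S18	0.648042216422693	-0.665775106116854
S19	0.306232144189206	-0.193108923968828
S20	-0.387015697050985	-0.381635483764888
S21	-0.169200479963762	0.136531159487652
S22	0.19916772314774	-0.268932568615192
S23	-0.78154610706062	0.263858913634019
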