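taxon	oldest	youngest	low_confidence	note
Chavinziphius	6.93	6.71	FALSE	Messinian, Cerro Los Quesos
Chimuziphius	8.9	8.5	FALSE	Tortonian, Cerro Colorado
Ninoziphius	5.93	3.9	FALSE	Messinian or Zanclean, Peru
Notoziphius	10	10	FALSE	Tortonian, Argentina
Messapicetus_gregarius	9.1	8.5	FALSE	Tortonian, Peru
Messapicetus_longirostris	10.5	8.14	FALSE	Tortonian, Italy
Ziphirostrum	9.5	7.5	FALSE	Tortonian, Belgium
Aporotus_dicyrtus	23.03	2.58	TRUE	Neogene, Belgium
Aporotus_recurvirostris	23.03	2.58	TRUE	Neogene, Belgium
Beneziphius	23.03	2.58	TRUE	Neogene, Belgium
Choneziphius	9.5	7.5	FALSE	Tortonian, Belgium (C. planirostris)
Globicetus	6.1	4.4	TRUE	probably Messinian-Zanclean, Iberia
Imocetus	6.1	4.4	TRUE	probably Messinian-Zanclean, Portugal
Tusciziphius	6.1	3.84	TRUE	Messinian-Zanclean, Italy/Iberia/USA
Nazcacetus	7.55	7.3	FALSE	late Tortonian, Peru
Archaeoziphius	15	13.2	FALSE	middle Miocene, Belgium
Microberardius	15.97	2.58	TRUE	probably middle Miocene-Pliocene, South Africa
Nenga	15.97	2.58	TRUE	probably middle Miocene-Pliocene, South Africa
Pterocetus	15.97	2.58	TRUE	probably middle Miocene-Pliocene, South Africa
Xhosacetus	15.97	2.58	TRUE	probably middle Miocene-Pliocene, South Africa
Izikoziphius	15.97	2.58	TRUE	probably middle Miocene-Pliocene, South Africa
Mesoplodon_posti	4.86	3.9	FALSE	Zanclean, Belgium
Tasmacetus	0	0	FALSE	extant
Berardius	0	0	FALSE	extant
Hyperoodon	0	0	FALSE	extant
Indopacetus	0	0	FALSE	extant
Mesoplodon	0	0	FALSE	extant
Ziphius	0	0	FALSE	extant
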