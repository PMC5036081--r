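taxon	area
Chavinziphius	A
Ninoziphius	A
Chimuziphius	A
Notoziphius	B
Messapicetus_gregarius	A
Messapicetus_longirostris	A
Ziphirostrum	A
Aporotus_dicyrtus	A
Aporotus_recurvirostris	A
Beneziphius	A
Choneziphius	A
Globicetus	A
Imocetus	A
Tusciziphius	A
Tasmacetus	B
Nazcacetus	A
Archaeoziphius	A
Berardius	D
Microberardius	B
Nenga	B
Pterocetus	B
Xhosacetus	B
Izikoziphius	B
Hyperoodon	D
Indopacetus	C
Mesoplodon	C
Mesoplodon_posti	A
Ziphius	C
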