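node	max_age	min_age	members
Ziphiidae	17.5	11.9	Chavinziphius,Ninoziphius,Chimuziphius,Notoziphius,Messapicetus_gregarius,Messapicetus_longirostris,Ziphirostrum,Aporotus_dicyrtus,Aporotus_recurvirostris,Beneziphius,Choneziphius,Globicetus,Imocetus,Tusciziphius,Tasmacetus,Nazcacetus,Archaeoziphius,Berardius,Microberardius,Ziphius,Izikoziphius,Indopacetus,Nenga,Pterocetus,Xhosacetus,Hyperoodon,Mesoplodon,Mesoplodon_posti
Messapicetus_clade	13.8	13.8	Chimuziphius,Notoziphius,Messapicetus_gregarius,Messapicetus_longirostris,Ziphirostrum,Aporotus_dicyrtus,Aporotus_recurvirostris,Beneziphius,Choneziphius,Globicetus,Imocetus,Tusciziphius
Crown_Ziphiidae	17	17	Tasmacetus,Nazcacetus,Archaeoziphius,Berardius,Microberardius,Ziphius,Izikoziphius,Indopacetus,Nenga,Pterocetus,Xhosacetus,Hyperoodon,Mesoplodon,Mesoplodon_posti
Berardiinae	15	13.2	Archaeoziphius,Berardius,Microberardius
Mesoplodon	4.86	3.9	Mesoplodon,Mesoplodon_posti
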