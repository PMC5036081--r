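(Chavinziphius,(Ninoziphius,(((Chimuziphius,Notoziphius),((Messapicetus_gregarius,Messapicetus_longirostris),(Ziphirostrum,((Aporotus_dicyrtus,Aporotus_recurvirostris),(Beneziphius,(Choneziphius,(Globicetus,(Imocetus,Tusciziphius)))))))),(Tasmacetus,(Nazcacetus,((Archaeoziphius,(Berardius,Microberardius)),((Ziphius,Izikoziphius),(Indopacetus,(Nenga,((Pterocetus,Xhosacetus),(Hyperoodon,(Mesoplodon,Mesoplodon_posti))))))))))));
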