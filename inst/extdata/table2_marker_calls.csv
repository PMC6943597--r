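germplasm,actual_species,beta_elemene,valencene,nootkatone,limettin
Fu tangerine,LSM,Y,N,N,N
Huapi tangerine,LSM,Y,N,N,N
Zhuhong tangerine,LSM,Y,N,N,N
Nian tangerine,LSM,Y,N,N,N
Shatang tangerine,LSM,Y,N,N,N
Suhong tangerine,LSM,N,N,N,N
Nanfengmi tangerine,LSM,Y,N,N,N
Huanongbendizao tangerine,LSM,Y,N,N,N
Tu tangerine,LSM,Y,N,N,N
Red tangerine,LSM,Y,N,N,N
Anliu sweet orange,SW,N,Y,N,N
Valencia sweet orange,SW,N,Y,N,N
Hamlin sweet orange,SW,Y,Y,N,N
Hong anliu sweet orange,SW,N,Y,N,N
Cara cara navel orange,SW,N,Y,N,N
Jincheng sweet orange,SW,N,Y,N,N
Washington navel orange,SW,N,Y,N,N
Seika navel orange,SW,N,Y,N,N
Newhall navel orange,SW,N,Y,N,N
Feicui pomelo,P,N,N,Y,N
Kaopan pomelo,P,N,N,Y,N
Huanong red pomelo,P,N,N,Y,N
Liangping pomelo,P,N,N,Y,N
Wanbai pomelo,P,N,N,Y,N
Low-acid pomelo,P,N,N,Y,N
Finger citron,Lem,N,N,N,Y
Tahiti lime,Lem,N,N,Y,Y
Kesai lime,Lem,Y,Y,N,Y
Verna lemon,Lem,N,N,N,Y
Eureka lemon,Lem,N,N,N,Y
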