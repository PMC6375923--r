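compound_id,compound_name,class,category,standard,wavelength_nm
c01,Chlorogenic acid,phenolic_acid,CA,CA,340
c02,Luteolin C-hexoside-O-hexoside (1),flavonoid,LG,VX1,340
c03,Isoorientin-2''-O-xyloside,flavonoid,LG,VX1,340
c04,Luteolin C-hexoside-O-hexoside (2),flavonoid,LG,VX1,340
c05,Isoorientin-4''-O-xyloside,flavonoid,LG,VX1,340
c06,Isoorientin,flavonoid,LG,VX1,340
c07,Orientin,flavonoid,LG,VX1,340
c08,Isoorientin-2''-O-rhamnoside,flavonoid,LG,VX1,340
c09,Luteolin C-hexoside-O-pentoside,flavonoid,LG,VX1,340
c10,Isovitexin-2''-O-glucoside,flavonoid,AG,VX1,340
c11,Isovitexin-2''-O-xyloside,flavonoid,AG,VX1,340
c12,Vitexin,flavonoid,AG,VX1,340
c13,Apigenin C-hexoside-O-pentoside,flavonoid,AG,VX1,340
c14,Diosmetin C-hexoside-O-pentoside,flavonoid,DG,VX1,340
c15,Isovitexin 2''-O-rhamnoside,flavonoid,AG,VX1,340
c16,Apigenin C-hexoside-O-xyloside,flavonoid,AG,VX1,340
c17,Isovitexin,flavonoid,AG,VX1,340
c18,Diosmetin-C-hexoside-O-deoxyhexoside,flavonoid,DG,VX1,340
c19,Diosmetin-C-hexoside,flavonoid,DG,VX1,340
c20,Luteolin-O-malonyl-C-hexoside (1),flavonoid,LMG,VX1,340
c21,Luteolin-O-malonyl-C-hexoside (2),flavonoid,LMG,VX1,340
c22,Apigenin-O-malonyl-C-hexoside (1),flavonoid,AMG,VX1,340
c23,Apigenin-O-deoxyhexoside-O-malonyl-C-hexoside (1),flavonoid,AMG,VX1,340
c24,Apigenin-O-malonyl-C-hexoside (2),flavonoid,AMG,VX1,340
c25,Apigenin-O-deoxyhexoside-O-malonyl-C-hexoside (2),flavonoid,AMG,VX1,340
c26,Apigenin-O-malonyl-C-hexoside (3),flavonoid,AMG,VX1,340
c27,Quercetin O-hexoside-O-deoxyhexoside,flavonoid,QG,RU,340
c28,Rutin,flavonoid,QG,RU,340
c29,Quercetin O-hexoside (1),flavonoid,QG,RU,340
c30,Quercetin O-hexoside (2),flavonoid,QG,RU,340
c31,Quercetin O-pentoside (1),flavonoid,QG,RU,340
c32,Quercetin O-pentoside (2),flavonoid,QG,RU,340
c33,Quercetin O-hexoside-O-hexoside,flavonoid,QG,RU,340
c34,Flavonolignan 1,flavonolignan,FL,VX2,390
c35,Flavonolignan 2,flavonolignan,FL,VX2,390
c36,Flavonolignan 3,flavonolignan,FL,VX2,390
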