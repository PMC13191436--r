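"analyte","threshold","descriptor"
"(Z)-4-Heptenal",0.0034,"Grassy-like"
"Alpha-pinene",1.0138,"Pinewood-like"
"1-Butanol",10,"Fruity-like"
"3-Methyl-1-butanol",0.3,"Burnt malt-like"
"1-Hexanal",0.0075,"Fresh apple-like"
"1-Nonanal",0.015,"Fatty-like"
"1-Octanal",7e-04,"Orange-like"
"1-Octen-3-ol",0.007,"Mushroom-like"
"1-Octen-3-one",0.03,"Mushroom-like"
"1-Pentanol",5,"Flowers-like, fruity-like"
"2-Butanone",3,"Pleasant fruity-like"
"2-Heptanone",0.2,"Blue cheese-like, nutty-like"
"2-Hexanol",6.7,""
"2-Hexanone",0.09,"Pungent alcohol-like"
"2-Methylbutanal",0.003,"Almond-like, malt-like"
"2-Methylpyrazine",0.25,"Hazelnut-like"
"2-Pentanone",0.09,"Pungent alcohol-like"
"3-Methylbutanal",0.008,"Apple-like"
"3-Octanol",0.1,"Mushroom-like"
"3-Octanone",1,"Vanilla-like"
"Ethyl acetate",0.1,"Brandy-like"
"Butanal",0.00526,"Banana-like"
"Ethyl formate",6.6,"Pungent"
"Heptanal",0.01,"Fatty-like"
"Methyl isovalerate",4e-04,"Fruity-like"
"n-Pentanal",0.008,"Almond-like, malt-like"
"(E)-2-Octenal",NA,""
"2-Hexenal",NA,""
"2-Methyl-2-propenal",NA,""
"Propanal",NA,""
"(Z)-3-Hexen-1-ol butanoate",NA,""
"3-(Methylthio)-1-propene",NA,""
"Beta-ocimene",NA,""
"1-Octene",NA,""
"Camphene",NA,""
"Pyrrolidine",NA,""
"Tetrahydrofuran",NA,""
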