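name,type,variants
Sok,given,Sokh|Soc
Chan,given,Chann|Chhan
Dara,given,Darra|Daara
Bopha,given,Bopa|Bophar
Sophea,given,Sopheah|Sofea
Phally,given,Phaly|Faly
Vanna,given,Vana|Vannah
Srey,given,Srei|Sray
Kunthea,given,Kuntheah|Kunthia
Rith,given,Rit|Ritt
Samnang,given,Somnang|Samnaang
Veasna,given,Visna|Veasnah
Pisey,given,Pisei|Pisay
Chenda,given,Chendar|Jenda
Thida,given,Tida|Thyda
Sovan,given,Sovann|Sowan
Nary,given,Nari|Neary
Mealea,given,Malea|Mealear
Rachana,given,Rachhana|Racheana
Piseth,given,Piset|Pisith
Vibol,given,Vibole|Vybol
Narith,given,Narit|Nareth
Chantha,given,Chanta|Chanthea
Sreymom,given,Sreimom|Sreymum
Kosal,given,Kossal|Kosol
Makara,given,Makkara|Macara
Panha,given,Panna|Panhna
Ratanak,given,Rattanak|Ratanac
Seyha,given,Seiha|Seyhar
Sothy,given,Sothi|Soty
Tola,given,Tolla|Tula
Vichet,given,Vichit|Vicheth
Visal,given,Vissal|Visall
Chhay,given,Chay|Chhai
Sreyneang,given,Sreineang|Sreyneng
Tevy,given,Tevi|Tevey
Vandy,given,Vandi|Vanndy
Mony,given,Moni|Monny
Nimol,given,Nimole|Nymol
Oudom,given,Odom|Oudum
Phirun,given,Pirun|Phiroun
Sambath,given,Sambat|Sombath
Sina,given,Sinna|Syna
Socheat,given,Sochet|Socheath
Sophal,given,Sophall|Sopheal
Chamroeun,given,Chamreun|Chomroeun
Dany,given,Dani|Danny
Kanha,given,Kana|Kanya
Leakhena,given,Leakena|Likhena
Malis,given,Maliss|Malys
Neang,given,Neng|Neange
Rattana,given,Ratana|Rathana
Sarath,given,Sarat|Sareth
Savuth,given,Savut|Savouth
Sineth,given,Sinet|Syneth
Sokun,given,Sokon|Sokoun
Sopheak,given,Sophek|Sopheark
Vannak,given,Vanak|Vannac
Vireak,given,Virak|Vireac
Chariya,given,Charya|Chariyah
Chea,family,Chear|Chia
Chhim,family,Chim|Chhym
Dith,family,Dit|Dyth
Duong,family,Doung|Dung
Em,family,Emm|Aem
Heng,family,Hengg|Haeng
Hun,family,Hunn|Houn
Keo,family,Keov|Kaev
Kong,family,Kawng|Kongg
Lim,family,Limm|Lym
Ly,family,Li|Lee
Mao,family,Mav|Maov
Meas,family,Mias|Meass
Nhem,family,Nem|Nhemm
Nov,family,Nou|Novv
Ouk,family,Uk|Oukk
Phan,family,Phann|Fan
Prak,family,Prakk|Prac
Ros,family,Rous|Ross
San,family,Sann|Saan
Sar,family,Sarr|Saar
Seng,family,Sengg|Saeng
Sim,family,Sym|Simm
So,family,Soo|Sou
Sok,family,Sokh|Soc
Tan,family,Tann|Taan
Tep,family,Tepp|Teap
Touch,family,Tuch|Touc
Un,family,Unn|Oun
Ung,family,Ungg|Oung
Var,family,Va|Varr
Yim,family,Yem|Yimm
Yos,family,Yoss|Yous
Khiev,family,Kiev|Khieu
Chap,family,Chapp|Chhap
Leng,family,Lengg|Laeng
Mom,family,Momm|Maum
Nget,family,Ngeth|Nguet
Oum,family,Um|Oumm
Pich,family,Pech|Pitch
Pov,family,Pou|Povv
Rin,family,Rinn|Ryn
Svay,family,Svai|Svayy
Ta,family,Tah|Taa
Thong,family,Tong|Thongg
Vong,family,Vongg|Voung
Yun,family,Yunn|Youn
Chhun,family,Chun|Chhunn
Chorn,family,Chon|Chornn
Hem,family,Hemm|Haem
Hok,family,Hokk|Houk
Huot,family,Hout|Huott
Kem,family,Kemm|Kaem
Khun,family,Kun|Khunn
Lach,family,Lac|Lachh
Mak,family,Makk|Mac
Men,family,Menn|Maen
Neth,family,Net|Nethh
Nuon,family,Noun|Nuonn
Phou,family,Phu|Phow
Dul,family,Dull|Doul
Eng,family,Aeng|Engg
Im,family,Imm|Eim
Keat,family,Kiet|Keath
Lun,family,Lunn|Loun
Ny,family,Nee|Nyy
Ouch,family,Uch|Ouchh
Rong,family,Rongg|Raung
Tith,family,Tit|Tyth
Vy,family,Vi|Vey
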