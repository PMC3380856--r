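population,subdivision,country,lat,lon,n,n_rr,n_ra,n_aa,printed_cys
Yaqui,mesoamerican_agriculturalist,Mexico,27.48,-110.67,45,30,11,4,0.21
Tarahumara,mesoamerican_agriculturalist,Mexico,26.82,-107.07,109,81,23,5,0.15
Teenek,mesoamerican_agriculturalist,Mexico,21.60,-98.97,67,45,20,2,0.18
Cora,mesoamerican_agriculturalist,Mexico,22.05,-104.92,123,62,51,10,0.29
Purepecha,mesoamerican_agriculturalist,Mexico,19.60,-102.23,35,22,11,2,0.21
Mazahua,mesoamerican_agriculturalist,Mexico,19.43,-100.00,83,68,15,0,0.09
Mixe,mesoamerican_agriculturalist,Mexico,17.00,-96.00,19,15,4,0,0.11
Mixtec,mesoamerican_agriculturalist,Mexico,17.00,-97.00,4,4,0,0,0.00
Nahuatl,mesoamerican_agriculturalist,Mexico,19.97,-97.62,267,185,73,9,0.17
Totonaco,mesoamerican_agriculturalist,Mexico,19.95,-97.73,113,86,24,3,0.13
Otomies,mesoamerican_agriculturalist,Mexico,20.47,-99.22,42,35,7,0,0.08
Zapotec,mesoamerican_agriculturalist,Mexico,17.23,-96.23,125,71,50,4,0.24
Mayan,mesoamerican_agriculturalist,Mexico,20.22,-90.47,110,68,39,3,0.20
Kaqchikel-Quiche,mesoamerican_agriculturalist,Guatemala,15.00,-91.00,17,13,3,1,0.15
Cabecar,mesoamerican_agriculturalist,Costa Rica,9.50,-84.00,24,19,5,0,0.10
Guaymi,mesoamerican_agriculturalist,Costa Rica/Panama,8.50,-82.00,35,26,8,1,0.15
Parkateje (Gaviao),sa_hunter_gatherer,Brazil,-5.05,-48.60,78,65,12,1,0.09
Jamamadi,sa_hunter_gatherer,Brazil,-7.25,-66.68,26,26,0,0,0.00
Mekranoti (Kayapo),sa_hunter_gatherer,Brazil,-8.67,-54.00,25,24,1,0,0.02
Mura (Piraha),sa_hunter_gatherer,Brazil,-3.57,-59.20,18,11,6,1,0.22
Pacaas-Novos (Wari),sa_hunter_gatherer,Brazil,-11.13,-65.08,25,23,2,0,0.04
Satere-Mawe,sa_hunter_gatherer,Brazil,-3.00,-57.00,25,20,4,1,0.12
Apalai,sa_hunter_gatherer,Brazil,1.33,-54.67,22,15,7,0,0.16
Arara,sa_hunter_gatherer,Brazil,-3.50,-54.17,24,15,9,0,0.19
Guarani,sa_hunter_gatherer,Brazil,-25.33,-52.50,31,30,1,0,0.02
Gorotire (Kayapo),sa_hunter_gatherer,Brazil,-7.73,-51.17,7,6,0,1,0.14
Karitiana,sa_hunter_gatherer,Brazil,-8.75,-63.85,20,20,0,0,0.00
Xavante,sa_hunter_gatherer,Brazil,-13.33,-51.67,21,10,9,2,0.31
Xikrin (Kayapo),sa_hunter_gatherer,Brazil,-5.92,-51.18,17,16,1,0,0.03
Yanomama,sa_hunter_gatherer,Brazil,3.50,-64.00,25,20,4,1,0.12
Txukahamae (Kayapo),sa_hunter_gatherer,Brazil,-10.33,-53.08,30,26,4,0,0.07
Tiriyo (Trio),sa_hunter_gatherer,Brazil,1.95,-55.82,25,21,4,0,0.08
Icana River (Baniwa),sa_hunter_gatherer,Brazil,1.00,-67.83,19,13,3,3,0.24
Kuben Kran Keng (Kayapo),sa_hunter_gatherer,Brazil,-8.17,-58.13,17,13,4,0,0.12
Lengua,sa_hunter_gatherer,Paraguay,-23.00,-56.00,29,29,0,0,0.00
Ache (Guayaki),sa_hunter_gatherer,Paraguay,-23.00,-58.00,23,23,0,0,0.00
Ayoreo,sa_hunter_gatherer,Paraguay,-19.00,-60.50,30,30,0,0,0.00
Zenu,sa_hunter_gatherer,Colombia,9.00,-75.00,4,4,0,0,0.00
Kogi,sa_hunter_gatherer,Colombia,11.00,-74.00,7,7,0,0,0.00
Ticuna,sa_hunter_gatherer,Colombia,-3.88,-70.00,1,1,0,0,0.00
Embera,sa_hunter_gatherer,Colombia,7.00,-76.00,3,3,0,0,0.00
Wayuu,sa_hunter_gatherer,Colombia,11.00,-73.00,17,15,2,0,0.06
Palikur,sa_hunter_gatherer,French Guiana,4.00,-51.75,3,1,2,0,0.33
Mapuche,andean_agriculturalist,Chile,-40.50,-69.33,40,40,0,0,0.00
Aymara (Bolivia),andean_agriculturalist,Bolivia,-16.50,-68.15,16,16,0,0,0.00
Quechua,andean_agriculturalist,Bolivia,-14.50,-69.00,16,15,1,0,0.03
Aymara (Chile),andean_agriculturalist,Chile,-22.00,-70.00,22,20,2,0,0.05
Chilote,andean_agriculturalist,Chile,-42.50,-73.92,2,2,0,0,0.00
Hulliche,andean_agriculturalist,Chile,-41.00,-73.00,13,10,3,0,0.11
Ingano,andean_agriculturalist,Colombia,1.00,-77.00,6,5,1,0,0.08
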