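region,uf,name,sim_2010,sim_2019,ihme_2010,ihme_2019,gbdbr_2010,gbdbr_2019,var_sim,var_ihme,var_gbdbr
Brasil,BR,Brasil,66.5,57.8,83.1,75.2,75.6,67.4,-13.1,-9.6,-10.9
Norte,AC,Acre,65.0,68.2,75.3,79.0,69.2,73.2,4.9,4.9,5.8
Norte,AP,Amapa,73.8,72.1,75.5,78.0,77.4,77.6,-2.3,3.3,0.3
Norte,AM,Amazonas,66.0,71.1,77.1,70.5,71.3,74.0,7.8,-8.6,3.7
Norte,PA,Para,76.5,71.0,93.3,83.7,84.1,77.0,-7.2,-10.2,-8.5
Norte,RO,Rondonia,97.1,70.1,103.0,94.7,104.7,89.2,-27.8,-8.0,-14.8
Norte,RR,Roraima,82.5,100.6,84.2,88.2,91.1,106.9,22.0,4.7,17.3
Norte,TO,Tocantins,84.3,82.5,86.1,82.8,90.9,95.7,-2.1,-3.9,5.3
Nordeste,AL,Alagoas,103.8,68.3,129.4,102.1,119.5,84.4,-34.2,-21.1,-29.4
Nordeste,BA,Bahia,74.4,75.7,94.1,88.0,89.0,87.7,1.6,-6.4,-1.5
Nordeste,CE,Ceara,73.4,61.5,98.3,104.3,94.0,77.0,-16.2,6.1,-18.0
Nordeste,MA,Maranhao,58.0,61.6,87.5,87.8,74.8,79.3,6.2,0.4,6.1
Nordeste,PB,Paraiba,70.3,60.3,92.4,82.9,80.3,68.3,-14.1,-10.3,-14.9
Nordeste,PE,Pernambuco,75.4,71.4,100.9,100.6,91.0,92.0,-5.3,-0.3,1.1
Nordeste,PI,Piaui,59.9,62.0,68.4,73.2,65.3,69.8,3.4,7.0,7.0
Nordeste,RN,Rio Grande do Norte,59.5,65.9,80.7,86.6,76.8,71.7,10.8,7.3,-6.7
Nordeste,SE,Sergipe,82.0,79.2,91.6,100.9,86.1,88.2,-3.4,10.2,2.4
Sudeste,ES,Espirito Santo,101.6,69.9,115.0,95.1,112.3,90.0,-31.2,-17.3,-19.8
Sudeste,MG,Minas Gerais,56.6,49.9,77.2,68.3,66.1,60.3,-11.8,-11.5,-8.7
Sudeste,RJ,Rio de Janeiro,68.4,50.6,94.0,81.5,79.8,69.5,-26.1,-13.4,-12.9
Sudeste,SP,Sao Paulo,50.1,38.7,62.8,52.4,55.7,43.7,-22.7,-16.6,-21.5
Sul,PR,Parana,84.4,66.4,93.2,76.3,88.4,71.7,-21.4,-18.2,-18.9
Sul,RS,Rio Grande do Sul,59.8,57.3,69.0,65.6,63.1,60.6,-4.2,-4.9,-4.0
Sul,SC,Santa Catarina,60.6,54.3,71.4,60.2,65.6,58.3,-10.3,-15.6,-11.1
Centro-oeste,DF,Distrito Federal,71.0,47.0,73.7,59.2,76.4,54.2,-33.7,-19.6,-29.0
Centro-oeste,GO,Goias,82.1,77.3,95.2,93.0,90.0,87.6,-5.8,-2.3,-2.6
Centro-oeste,MT,Mato Grosso,92.2,76.4,99.7,89.8,96.5,81.4,-17.2,-10.0,-15.6
Centro-oeste,MS,Mato Grosso do Sul,81.9,63.2,87.3,72.3,84.2,66.5,-22.8,-17.1,-21.1
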