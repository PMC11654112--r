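region,uf,name,ext_2010,ext_2019,transport_2010,transport_2019,falls_2010,falls_2019,homicide_2010,homicide_2019,suicide_2010,suicide_2019
Brasil,BR,Brasil,1.14,1.17,1.17,1.25,1.35,1.37,1.20,1.30,1.17,1.23
Norte,AC,Acre,1.06,1.07,1.06,1.08,1.12,1.44,1.10,1.07,1.10,1.08
Norte,AP,Amapa,1.05,1.08,1.05,1.14,1.75,1.24,1.06,1.07,1.09,1.07
Norte,AM,Amazonas,1.08,1.04,1.09,1.06,1.20,1.21,1.10,1.09,1.09,1.08
Norte,PA,Para,1.10,1.08,1.12,1.10,1.37,1.30,1.10,1.12,1.13,1.15
Norte,RO,Rondonia,1.08,1.27,1.10,1.27,1.18,1.35,1.11,1.38,1.10,1.30
Norte,RR,Roraima,1.10,1.06,1.05,1.11,1.89,1.18,1.16,1.18,1.10,1.13
Norte,TO,Tocantins,1.08,1.16,1.08,1.18,1.16,1.28,1.10,1.19,1.12,1.21
Nordeste,AL,Alagoas,1.15,1.24,1.17,1.27,1.30,1.29,1.13,1.26,1.17,1.26
Nordeste,BA,Bahia,1.20,1.16,1.31,1.28,1.78,1.70,1.23,1.25,1.38,1.35
Nordeste,CE,Ceara,1.28,1.25,1.30,1.33,1.79,1.68,1.27,1.34,1.24,1.28
Nordeste,MA,Maranhao,1.29,1.29,1.31,1.33,1.90,1.76,1.23,1.24,1.31,1.29
Nordeste,PB,Paraiba,1.14,1.13,1.15,1.14,1.42,1.22,1.15,1.17,1.17,1.15
Nordeste,PE,Pernambuco,1.21,1.29,1.27,1.44,1.69,1.50,1.25,1.40,1.29,1.40
Nordeste,PI,Piaui,1.09,1.13,1.07,1.09,1.30,1.42,1.13,1.17,1.07,1.09
Nordeste,RN,Rio Grande do Norte,1.29,1.09,1.35,1.13,1.84,1.50,1.38,1.11,1.27,1.16
Nordeste,SE,Sergipe,1.05,1.11,1.08,1.19,1.15,1.29,1.10,1.20,1.12,1.23
Sudeste,ES,Espirito Santo,1.11,1.29,1.12,1.38,1.17,1.32,1.14,1.45,1.14,1.37
Sudeste,MG,Minas Gerais,1.17,1.21,1.18,1.26,1.36,1.30,1.25,1.40,1.20,1.21
Sudeste,RJ,Rio de Janeiro,1.17,1.38,1.24,1.93,1.42,2.32,1.25,1.72,1.23,1.63
Sudeste,SP,Sao Paulo,1.11,1.13,1.17,1.30,1.34,1.38,1.27,1.62,1.19,1.33
Sul,PR,Parana,1.05,1.08,1.06,1.13,1.13,1.12,1.10,1.26,1.06,1.18
Sul,RS,Rio Grande do Sul,1.05,1.06,1.08,1.09,1.28,1.13,1.16,1.11,1.11,1.08
Sul,SC,Santa Catarina,1.08,1.07,1.10,1.10,1.19,1.13,1.12,1.17,1.07,1.12
Centro-oeste,DF,Distrito Federal,1.08,1.15,1.09,1.21,1.10,1.13,1.16,1.28,1.09,1.21
Centro-oeste,GO,Goias,1.10,1.13,1.09,1.15,1.18,1.16,1.14,1.19,1.10,1.14
Centro-oeste,MT,Mato Grosso,1.05,1.07,1.05,1.09,1.12,1.12,1.11,1.14,1.14,1.11
Centro-oeste,MS,Mato Grosso do Sul,1.03,1.05,1.05,1.09,1.18,1.28,1.09,1.16,1.10,1.14
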