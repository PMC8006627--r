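# synthetic miniature gazetteer bundled for self-contained use
# surface<TAB>weight
Avenida Aragon 132, 03012	1
Avenida Ausias March 31, 46003	1
Avenida Baron de Carcer 68, 46009	1
Avenida Blasco Ibanez 155, 46013	1
Avenida Burjassot 164, 03005	1
Avenida de la Constitucion 160, 46020	1
Avenida del Cid 81, 12005	1
Avenida del Puerto 12, 46002	1
Avenida Gaspar Aguilar 87, 03009	1
Avenida General Aviles 78, 46014	1
Avenida Giorgeta 164, 03014	1
Avenida Malvarrosa 145, 03006	1
Avenida Manuel Candela 108, 46014	1
Avenida Peris y Valero 180, 46006	1
Avenida Primado Reig 153, 03014	1
Avenida Tres Cruces 66, 03009	1
Calle Alboraya 35, 46007	1
Calle Campoamor 126, 03004	1
Calle Colon 42, 03001	1
Calle Cuenca 155, 12005	1
Calle de la Paz 119, 12001	1
Calle Doctor Gomez Ferrer 53, 46002	1
Calle Guillem de Castro 116, 03007	1
Calle Islas Canarias 27, 12006	1
Calle Jesus 156, 46013	1
Calle Literato Azorin 166, 46004	1
Calle Mayor 108, 46003	1
Calle Padre Tomas Montanana 131, 12004	1
Calle Pintor Sorolla 124, 46023	1
Calle Ruzafa 153, 46008	1
Calle Sagunto 111, 46021	1
Calle San Juan Bosco 120, 46023	1
Calle San Vicente Martir 3, 46019	1
Calle Turia 7, 46004	1
Calle Xativa 144, 46021	1
Carrer de Baix 31, 46002	1
Carrer de Colom 138, 12006	1
Carrer de Dalt 46, 03012	1
Carrer de l'Hort 48, 46025	1
Carrer de la Mar 85, 12003	1
Carrer de Quart 132, 46025	1
Carrer de Russafa 176, 03012	1
Carrer de Sagunt 132, 46002	1
Carrer del Mig 131, 03012	1
Carrer del Pintor Benedito 22, 03004	1
Carrer Major 157, 03006	1
Carrer Nou 56, 12002	1
Carrer Sant Pau 122, 46018	1
Gran Via Marques del Turia 149, 46006	1
Plaza del Ayuntamiento 121, 46001	1
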