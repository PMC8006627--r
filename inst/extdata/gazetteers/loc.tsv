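# synthetic miniature gazetteer bundled for self-contained use
# surface<TAB>weight
Alaquas	29474
Alboraya	24454
Alcoy	58977
Aldaia	31320
Alicante	334887
Altea	22290
Alzira	44255
Benidorm	67558
Bunyol	9800
Burjassot	37575
Burriana	34683
Calp	21633
Carcaixent	20331
Castellon de la Plana	171728
Catarroja	27752
Crevillent	28955
Cullera	22145
Denia	41591
Elche	230625
Elda	52618
Gandia	74562
Ibi	23489
La Vila Joiosa	33653
Llombai	3200
Mancha Real	11000
Manises	30693
Mislata	43775
Moncada	21823
Novelda	25725
Oliva	25789
Ontinyent	35347
Orihuela	76778
Paterna	68547
Petrer	34276
Picassent	20658
Puerto de Sagunto	40000
Quart de Poblet	24491
Riba-roja de Turia	22076
Sagunto	65669
San Vicente del Raspeig	57785
Santa Pola	31745
Sueca	27333
Torrent	80630
Torrevieja	83337
Valencia	789744
Vila-real	50893
Villena	33964
Xabia	27224
Xativa	29070
Xirivella	29374
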