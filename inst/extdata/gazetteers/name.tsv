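# synthetic miniature gazetteer bundled for self-contained use
# surface<TAB>weight
Abdul	13618
Adrian	21086
Aguilar	13365
Aicha	7583
Ainhoa	7821
Aitor	14885
Alba	8078
Alberto	23710
Alcaraz	9663
Alejandro	30272
Alicia	8353
Alonso	37936
Alvarez	41467
Alvaro	21886
Ana	12336
Andrea	7990
Andres	16905
Angel	32121
Angeles	10762
Antonia	10596
Antonio	250000
Arias	11443
Beatriz	9088
Benitez	11892
Blanco	27048
Bosch	9378
Bravo	10295
Caballero	13842
Cabeza	10048
Cabrera	14921
Calvo	16953
Campos	14728
Cano	17779
Carlos	43107
Carmen	12570
Carmona	11336
Carrasco	14182
Castillo	19032
Castro	23270
Catala	9737
Claudia	7905
Cortes	19378
Crespo	11232
Cristina	10934
Cruz	16697
Daniel	47366
David	68986
Delgado	23816
Diaz	48435
Diego	20350
Diez	14010
Dolores	11895
Dominguez	32559
Duran	12133
Elena	10281
Enrique	19037
Espinosa	9590
Esteban	10468
Eva	8864
Fatima	7661
Fernandez	131951
Fernando	28646
Ferrandis	9890
Ferrer	12257
Flores	15120
Francisca	10131
Francisco	82469
Fuentes	14359
Gallardo	10211
Gallego	16449
Garcia	400000
Garrido	19737
Gil	29518
Gimenez	12514
Gomez	68971
Gonzalez	166097
Guerrero	18075
Gutierrez	36411
Harrison	13338
Hector	14220
Hernandez	51393
Herrera	15535
Herrero	13068
Hidalgo	12648
Ibanez	12384
Iglesias	20913
Irene	8549
Isabel	12111
Ivan	16027
Javier	52706
Jimenez	58742
Joaquin	16453
Jorge	24758
Jose	103811
Josefa	11297
Juan	59624
Julia	8651
Laura	10436
Leon	15978
Llopis	9813
Lopez	110378
Lorenzo	12784
Lozano	18382
Lucia	9710
Luis	22757
Manuel	143587
Maria	12815
Marin	21789
Marquez	15753
Marta	9986
Martin	63396
Martinez	95398
Medina	20112
Mendez	17219
Mercedes	9846
Miguel	39622
Molina	26325
Montero	12924
Montserrat	8450
Mora	11776
Morales	25643
Moreno	45834
Moya	10648
Munoz	43528
Navarro	35017
Nieto	13520
Nunez	20504
Nuria	8259
Olga	7507
Omar	13070
Ortega	24392
Ortiz	22752
Oscar	17387
Pablo	27205
Parra	10381
Pascual	13215
Pastor	11029
Patricia	8974
Paula	9450
Pedro	34245
Penya	15324
Perez	75786
Pilar	11688
Prieto	17494
Rafael	36714
Ramirez	28640
Ramon	15625
Ramos	30458
Raquel	9326
Raul	19668
Reyes	13679
Rocio	9205
Rodriguez	229740
Roig	9518
Rojas	10129
Roman	11129
Romero	39613
Rosa	11112
Ruben	17900
Rubio	22259
Ruiz	54792
Saez	10835
Sanchez	84330
Santiago	27256
Santos	18701
Sanz	21341
Sara	9578
Segarra	9968
Sergio	25917
Serrano	27818
Silvia	8756
Soler	10557
Sonia	8167
Soto	10931
Steven	13912
Suarez	25000
Teresa	11488
Tomas	9448
Torres	33738
Vargas	11551
Vazquez	31470
Vega	14541
Velasco	10741
Vicente	30112
Vidal	16210
Xavier	14544
Xiaojing	7740
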