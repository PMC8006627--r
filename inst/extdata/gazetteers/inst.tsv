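# synthetic miniature gazetteer bundled for self-contained use
# surface<TAB>weight
Centro de Especialidades Juan Llorens	1
Centro de Salud Alaquas	1
Centro de Salud Alfafar	1
Centro de Salud Benimaclet	1
Centro de Salud Burjassot	1
Centro de Salud Campanar	1
Centro de Salud Catarroja	1
Centro de Salud Gandia Corea	1
Centro de Salud Malvarrosa	1
Centro de Salud Mislata	1
Centro de Salud Nazaret	1
Centro de Salud Oliva	1
Centro de Salud Paiporta	1
Centro de Salud Paterna	1
Centro de Salud Ruzafa	1
Centro de Salud Salvador Pau	1
Centro de Salud Serreria	1
Centro de Salud Torrent	1
Centro de Salud Trafalgar	1
Consultorio Auxiliar El Palmar	1
Hospital Arnau de Vilanova	1
Hospital Clinico Universitario de Valencia	1
Hospital de Denia	1
Hospital de la Plana	1
Hospital de Manises	1
Hospital de Sagunto	1
Hospital de Vinaros	1
Hospital Francesc de Borja	1
Hospital General de Requena	1
Hospital General Universitario de Alicante	1
Hospital General Universitario de Castellon	1
Hospital General Universitario de Elche	1
Hospital General Universitario de Valencia	1
Hospital Lluis Alcanyis	1
Hospital Universitari i Politecnic La Fe	1
Hospital Universitario de la Ribera	1
Hospital Universitario de Torrevieja	1
Hospital Universitario Doctor Peset	1
Hospital Universitario San Juan de Alicante	1
Hospital Virgen de los Lirios	1
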