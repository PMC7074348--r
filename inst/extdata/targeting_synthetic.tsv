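gene_id	targeting	tier	complex
AT1G01010	other	none
AT1G01020	plastid	direct	RUBISCO
AT1G67090	plastid	direct	RUBISCO
AT2G10940	other	none
AT1G69960	other	none
AT3G01500	plastid	complexed
AT4G05180	plastid	direct	PSII
AT5G66570	plastid	direct	PSII
AT2G36530	mitochondrion	complexed	OXPHOS_III
AT3G27240	mitochondrion	direct	OXPHOS_III
AT5G40650	mitochondrion	complexed	OXPHOS_II
AT1G47420	mitochondrion	complexed	OXPHOS_II
AT4G26910	dual	none
AT1G50920	unknown	none
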