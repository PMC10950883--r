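pair_id	experimental_id	synthetic_id	peptidoform_syn	peptidoform_exp	is_decoy
pair0001	exp|pair0001	syn|pair0001	ATEKYDIQTGAQGPYDEVCFLEKDLK/5:nitroY	ATEKYDIQTGAQGPYDEVCFLEKDLK/5:nitroY	FALSE
pair0002	exp|pair0002	syn|pair0002	SLPYLQFDPGSAQKAR/4:nitroY	ARTEYGSLPIVDARLPHLVCMNILPYFIK/26:nitroY	TRUE
pair0003	exp|pair0003	syn|pair0003	EIKVDYK/6:nitroY	EIKVDYK/6:nitroY	FALSE
pair0004	exp|pair0004	syn|pair0004	YDPQDAMSIQVK/1:nitroY	YDPQDAMSIQVK/1:nitroY	FALSE
pair0005	exp|pair0005	syn|pair0005	YDPQDAMSIQVKTCDTDTGDHK/1:nitroY	EIKVDYKGVHIR/6:nitroY	TRUE
pair0006	exp|pair0006	syn|pair0006	TEYGSLPIVDARLPHLVCMNILPYFIK/24:nitroY	TEYGSLPIVDARLPHLVCMNILPYFIK/24:nitroY	FALSE
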