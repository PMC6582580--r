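lineage	state
Priapulida	present
Nematoda	absent
Tardigrada	unknown
Araneae	present
Acari	present
Pancrustacea	absent
Platyhelminthes	absent
Annelida	present
Brachiopoda	present
Gastropoda	present
Bivalvia	absent
Cephalopoda	unknown
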