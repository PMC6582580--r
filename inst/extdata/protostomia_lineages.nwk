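((Priapulida,(Nematoda,(Tardigrada,((Araneae,Acari),Pancrustacea)))),(Platyhelminthes,(Annelida,(Brachiopoda,(Gastropoda,(Bivalvia,Cephalopoda))))));
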