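taxon	subdivision	rank
Viruses	non_eukaryote	NA
Bacteria	non_eukaryote	superkingdom
Archaea	non_eukaryote	superkingdom
Opisthokonta	Amorphea	clade
Metazoa	Amorphea	kingdom
Fungi	Amorphea	kingdom
Amoebozoa	Amorphea	clade
Choanoflagellata	Amorphea	clade
Ichthyosporea	Amorphea	clade
Chordata	Amorphea	phylum
Arthropoda	Amorphea	phylum
Mollusca	Amorphea	phylum
Nematoda	Amorphea	phylum
Annelida	Amorphea	phylum
Platyhelminthes	Amorphea	phylum
Echinodermata	Amorphea	phylum
Cnidaria	Amorphea	phylum
Porifera	Amorphea	phylum
Placozoa	Amorphea	phylum
Ctenophora	Amorphea	phylum
Nemertea	Amorphea	phylum
Ascomycota	Amorphea	phylum
Basidiomycota	Amorphea	phylum
Chytridiomycota	Amorphea	phylum
Archaeplastida	Diaphoretickes	clade
Viridiplantae	Diaphoretickes	kingdom
Streptophyta	Diaphoretickes	phylum
Chlorophyta	Diaphoretickes	phylum
Rhodophyta	Diaphoretickes	phylum
Glaucocystophyceae	Diaphoretickes	phylum
Sar	Diaphoretickes	clade
Stramenopiles	Diaphoretickes	clade
Alveolata	Diaphoretickes	clade
Rhizaria	Diaphoretickes	clade
Apicomplexa	Diaphoretickes	phylum
Haptista	Diaphoretickes	clade
Haptophyta	Diaphoretickes	phylum
Excavata	Diaphoretickes	clade
Discoba	Diaphoretickes	clade
Metamonada	Diaphoretickes	clade
Euglenozoa	Diaphoretickes	phylum
Jakobida	Diaphoretickes	order
CRuMs	CRuMs	clade
Collodictyonidae	CRuMs	family
Rigifilida	CRuMs	order
Mantamonas	CRuMs	genus
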