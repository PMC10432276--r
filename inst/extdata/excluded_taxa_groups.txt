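# Groups removed before analysis: taxa that are not freshwater
# macroinvertebrates or are inconsistently recorded because of small body
# size. Matched against the taxonomy map's order/class/group columns.
# This default list is illustrative, not exhaustive; supply your own file
# to extend it.
Trombidiformes        # water mites
Copepoda
Cladocera
Ostracoda
Collembola            # semi-aquatic
Actinopterygii        # vertebrates
Amphibia
Insecta-terrestrial
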