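name	formula	kegg_id	fragments	rt	standard
Allantoin	C4H6N4O3	C02350			FALSE
Arginine	C6H14N4O2	C00062	60.0556;70.0651;116.0706;130.0975;158.0924	5.0	TRUE
Histamine	C5H9N3	C00388			FALSE
Citrulline	C6H13N3O3	C00327			FALSE
Cystathionine	C7H14N2O4S	C02291			FALSE
Cystine	C6H12N2O4S2	C00491			FALSE
Cytidine	C9H13N3O5	C00475			FALSE
Glutamine	C5H10N2O3	C00064			FALSE
Glutamate	C5H9NO4	C00025			FALSE
Glycerophosphocholine	C8H20NO6P	C12181			FALSE
Guanosine	C10H13N5O5	C00387			FALSE
Hypotaurine	C2H7NO2S	C00519			FALSE
Taurine	C2H7NO3S	C00245			FALSE
Oxidized glutathione	C20H32N6O12S2	C00051			FALSE
S-Adenosylhomocysteine	C14H20N6O5S	C00021			FALSE
S-Adenosyl methionine	C15H22N6O5S	C00019			FALSE
5'-Methylthioadenosine	C11H15N5O3S	C00170			FALSE
Adenosine	C10H13N5O4	C00212			FALSE
Methionine	C5H11NO2S	C00073			FALSE
Homocysteine	C4H9NO2S	C00155			FALSE
Serine	C3H7NO3	C00065			FALSE
Histidine	C6H9N3O2	C00135			FALSE
Hydroxyproline	C5H9NO3	C01157			FALSE
Proline	C5H9NO2	C00148			FALSE
Carnosine	C9H14N4O3	C00386			FALSE
Valine	C5H11NO2	C00183			FALSE
Guanine	C5H5N5O	C00242			FALSE
Pantothenic acid	C9H17NO5	C00864			FALSE
3,4-Dihydroxymandelic acid	C8H8O5	C05580			FALSE
N-acetyl aspartate	C6H9NO5	C01042			FALSE
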