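well_id,carbon_source,category,is_control
A1,water,control,TRUE
A2,L-alanine,amino acids,FALSE
A3,L-arginine,amino acids,FALSE
A4,L-aspartic acid,amino acids,FALSE
A5,L-glutamic acid,amino acids,FALSE
A6,L-histidine,amino acids,FALSE
A7,L-serine,amino acids,FALSE
A8,L-proline,amino acids,FALSE
A9,L-threonine,amino acids,FALSE
A10,glycyl-L-proline,amino acids,FALSE
A11,L-phenylalanine,amino acids,FALSE
A12,L-leucine,amino acids,FALSE
B1,L-lysine,amino acids,FALSE
B2,D-glucose,monosaccharides,FALSE
B3,D-mannose,monosaccharides,FALSE
B4,D-galactose,monosaccharides,FALSE
B5,D-fructose,monosaccharides,FALSE
B6,L-rhamnose,monosaccharides,FALSE
B7,D-fucose,monosaccharides,FALSE
B8,D-xylose,monosaccharides,FALSE
B9,L-arabinose,monosaccharides,FALSE
B10,D-ribose,monosaccharides,FALSE
B11,D-arabitol,monosaccharides,FALSE
B12,D-sorbitol,monosaccharides,FALSE
C1,D-mannitol,monosaccharides,FALSE
C2,citric acid,carboxylic acids,FALSE
C3,L-malic acid,carboxylic acids,FALSE
C4,D-malic acid,carboxylic acids,FALSE
C5,succinic acid,carboxylic acids,FALSE
C6,fumaric acid,carboxylic acids,FALSE
C7,alpha-ketoglutaric acid,carboxylic acids,FALSE
C8,L-lactic acid,carboxylic acids,FALSE
C9,propionic acid,carboxylic acids,FALSE
C10,acetic acid,carboxylic acids,FALSE
C11,formic acid,carboxylic acids,FALSE
C12,bromosuccinic acid,carboxylic acids,FALSE
D1,quinic acid,carboxylic acids,FALSE
D2,D-saccharic acid,carboxylic acids,FALSE
D3,mucic acid,carboxylic acids,FALSE
D4,methyl pyruvate,esters,FALSE
D5,ethyl lactate,esters,FALSE
D6,tween 40,esters,FALSE
D7,tween 80,esters,FALSE
D8,D-lactic acid methyl ester,esters,FALSE
D9,acetoacetic acid ester,esters,FALSE
D10,butyric acid,fatty acids,FALSE
D11,alpha-hydroxybutyric acid,fatty acids,FALSE
D12,beta-hydroxybutyric acid,fatty acids,FALSE
E1,alpha-ketobutyric acid,fatty acids,FALSE
E2,caproic acid,fatty acids,FALSE
E3,nonanoic acid,fatty acids,FALSE
E4,D-gluconic acid,hexonic acid,FALSE
E5,D-galactonic acid lactone,hexonic acid,FALSE
E6,D-glucuronic acid,hexonic acid,FALSE
E7,D-galacturonic acid,hexonic acid,FALSE
E8,D-glucose-6-phosphate,hexosephosphate,FALSE
E9,D-fructose-6-phosphate,hexosephosphate,FALSE
E10,D-glucose-1-phosphate,hexosephosphate,FALSE
E11,DL-alpha-glycerol phosphate,hexosephosphate,FALSE
E12,sucrose,other,FALSE
F1,D-maltose,other,FALSE
F2,D-trehalose,other,FALSE
F3,D-cellobiose,other,FALSE
F4,gentiobiose,other,FALSE
F5,D-turanose,other,FALSE
F6,D-raffinose,other,FALSE
F7,alpha-D-lactose,other,FALSE
F8,D-melibiose,other,FALSE
F9,beta-methyl-D-glucoside,other,FALSE
F10,D-salicin,other,FALSE
F11,glycerol,other,FALSE
F12,inosine,other,FALSE
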