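feature_id,mode,rt,mz,adduct,source_herbs,putative_identity
P1,pos,3.36,191,[M+H]+,SOP,Cytisine
P2,pos,3.36,196,[M]+,PHE,Atraric acid
P3,pos,3.36,205,[M+H]+,SOP,N-Methylcytisine
P4,pos,3.36,215,[M]+,RHE,Mecoprop
P5,pos,3.36,261,[M+H]+,SOP,Baptifoline
P6,pos,3.75,265,[M+H]+,SOP,5a-Hydroxymatrine/9a-hydroxymatrine
P7,pos,4.15,265,[M+H]+,SOP,14b-Hydroxymatrine
P8,pos,4.40,180,[M]+,PHE,Candicine
P9,pos,4.75,245,[M+H]+,SOP,Anagyrine
P10,pos,4.75,265,[M+H]+,SOP,5a-Hydroxymatrine/9a-hydroxymatrine
P11,pos,5.00,247,[M+H]+,SOP,Isosophocarpine
P12,pos,5.52,263,[M+H]+,SOP,9a-Hydroxy-7-11-dehydromatrine
P13,pos,5.72,192,[M+H]+,PHE,Noroxyhydrastinine
P14,pos,5.72,249,[M+H]+,SOP,Matrine-type alkaloid
P15,pos,6.47,247,[M+H]+,SOP,Sophocarpine
P16,pos,6.47,249,[M+H]+,SOP,Matrine-type alkaloid
P17,pos,8.02,263,[M+H]+,SOP,Oxysophocarpine
P18,pos,8.02,265,[M+H]+,SOP,Oxymatrine/oxysophoridine
P19,pos,8.02,266,[M+NH4]+,SOP,Lupanine
P20,pos,10.42,247,[M+H]+,SOP,7-11-Dehydromatrine
P21,pos,11.30,263,[M+H]+,SOP,9a-Hydroxysophocarpine
P22,pos,11.48,263,[M+H]+,SOP,Leontalbinine N-oxide
P23,pos,11.48,265,[M+H]+,SOP,Oxymatrine/oxysophoridine
P24,pos,11.88,243,[M+H]+,DIC,Dasycarpusenester A
P25,pos,16.77,314,[M]+,PHE,Oblongine
P26,pos,20.08,342,[M+H]+,PHE,Phellodendrine
P27,pos,22.08,344,[M+H]+,PHE,Tembetarine
P28,pos,22.91,342,[M+H]+,PHE,Magnoflorine
P29,pos,26.84,314,[M+H]+,PHE,Evoeuropine
P30,pos,31.32,356,[M+H]+,PHE,Menisperine
P31,pos,52.87,336,[M]+,PHE,Berberine
N1,neg,2.34,193,[M-H]-,SCU,Glucuronic acid
N2,neg,2.46,191,[M-H]-,PHE,Quinic acid
N3,neg,2.46,223,[M-H]-,SOP,Sinapic acid
N4,neg,3.50,191,[M-H]-,PHE,Citric acid
N5,neg,3.50,331,[M-H]-,RHE,Galloylglucose/glucopyranosyloxyl gallic acid
N6,neg,4.08,331,[M-H]-,RHE,Galloylglucose/glucopyranosyloxyl gallic acid
N7,neg,4.61,331,[M-H]-,RHE,Galloylglucose/glucopyranosyloxyl gallic acid
N8,neg,5.35,125,[M-H]-,RHE,Pyrogallol
N9,neg,5.35,169,[M-H]-,RHE,Gallic acid
N10,neg,5.35,331,[M-H]-,RHE,Galloylglucose/glucopyranosyloxyl gallic acid
N11,neg,8.71,255,[M-H]-,SOP,Piscidic acid
N12,neg,13.88,577,[M-H]-,RHE,Procyanidin B
N13,neg,16.48,289,[M-H]-,RHE,Catechin
N14,neg,16.48,353,[M-H]-,PHE,Chlorogenic acid
N15,neg,18.15,367,[M-H]-,PHE,3-O-Feruloylquinic acid
N16,neg,21.10,325,[M-H]-,RHE,4-(4'-Hydroxylphenyl)-2-butanone 4'-O-glucoside
N17,neg,21.10,415,[M+Na-2H]-,RHE,6-Hydroxymusizin-8-O-glucoside
N18,neg,22.77,289,[M-H]-,RHE,Epicatechin
N19,neg,22.77,337,[M-H]-,PHE,p-Coumaroylquinic acid
N20,neg,24.72,303,[M-H]-,SCU,Pentahydroxyflavanone
N21,neg,26.26,367,[M-H]-,PHE,5-O-Feruloylquinic acid
N22,neg,26.65,389,[M-H]-,RHE,Resveratrol glucoside
N23,neg,32.06,301,[M-H]-,SCU,Pentahydroxyflavone
N24,neg,34.57,441,[M-H]-,RHE,Epicatechin 3-O-gallate
N25,neg,34.57,477,[M-H]-,RHE,Isolindleyin
N26,neg,34.57,547,[M-H]-,SCU,Chrysin-6-C-arabinosyl-8-C-glucoside
N27,neg,36.56,477,[M-H]-,RHE,Lindleyin
N28,neg,36.56,545,[M-H]-,RHE,Rhein glucoside derivative
N29,neg,37.25,547,[2M-H]-,SCU,Chrysin-6-C-glucosyl-8-C-arabonoside
N30,neg,38.43,541,[M-H]-,RHE,Resveratrol-4'-O-(2''-O-galloyl) glucoside
N31,neg,39.20,541,[M-H]-,RHE,Resveratrol-4'-O-(6''-O-galloyl) glucoside
N32,neg,45.08,301,[M-H]-,SCU,Trihydroxy-methoxyflavanone
N33,neg,46.91,431,[M-H]-,RHE,Emodin/aloe-emodin glucoside
N34,neg,55.48,481,[M+Cl]-,SOP,Maackiain-3-O-glucoside
N35,neg,58.94,431,[M-H]-,RHE,Emodin/aloe-emodin glucoside
N36,neg,63.95,233,[M-H]-,RHE,6-Hydroxy-3-4-dioxo-6-phenyl-5-hexenoic acid
N37,neg,71.02,269,[M-H]-,SCU,Trihydroxyflavone
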