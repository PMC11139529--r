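peak_no,rt_min,observed_mz,adduct,formula,name,class
1,0.34,167.0322,[M-H]-,C8H8O4,3-Methoxy-4-hydroxybenzoic acid,Organic acids
2,0.78,154.0612,[M-H]-,C6H9N3O2,Histidine,Amino acids
3,0.83,132.0287,[M-H]-,C4H7NO4,Aspartic acid,Amino acids
4,0.87,597.1071,[M+HCOO]-,C31H20O10,Isosalicylic acid biflavone,Flavonoids
5,0.92,285.0224,[M+HCOO]-,C6H12N2O4S2,Cystine,Amino acids
6,0.95,133.0131,[M-H]-,C4H6O5,2-Hydroxy-succinic acid,Organic acids
7,1.10,331.0663,[M-H]-,C13H16O10,1-O-Galloyl glucose 1,Tannins
8,1.15,175.0234,[M-H]-,C6H8O6,Ascorbic acid,Steroids
9,1.30,169.0131,[M-H]-,C7H6O5,Gallic acid,Phenolic acids and their esters
10,1.61,243.0498,[M+HCOO]-,C9H10O5,Syringic acid,Phenolic acids and their esters
11,1.72,783.0677,[M-H]-,C34H24O22,Pedunculagin,Tannins
12,2.10,483.0776,[M-H]-,C20H20O14,Di-O-galloyl glucose 1,Tannins
13,2.18,633.0723,[M-H]-,C27H22O18,Galloyl hexahydroxybiphenyl glucose 1,Tannins
14,2.93,321.0248,[M-H]-,C14H10O9,M-diGA or p-diGA,Phenolic acids and their esters
15,3.46,483.0772,[M-H]-,C20H20O14,Di-O-galloyl glucose 2,Tannins
16,3.72,321.0247,[M-H]-,C14H10O9,M-diGA or p-diGA,Phenolic acids and their esters
17,4.04,183.0283,[M-H]-,C8H8O5,Methyl gallate,Phenolic acids and their esters
18,4.47,633.0721,[M-H]-,C27H22O18,Galloyl hexahydroxybiphenyl glucose 2,Tannins
19,7.39,483.0768,[M-H]-,C20H20O14,Di-O-galloyl glucose 3,Tannins
20,7.40,635.0888,[M-H]-,C27H24O18,Tri-O-galloyl glucose 1,Tannins
21,9.99,635.0892,[M-H]-,C27H24O18,Tri-O-galloyl glucose 2,Tannins
22,10.56,635.0886,[M-H]-,C27H24O18,Tri-O-galloyl glucose 3,Tannins
23,11.80,635.0886,[M-H]-,C27H24O18,Tri-O-galloyl glucose 4,Tannins
24,12.67,182.02006,[M-H]-,C14H10O9,M-diGA or p-diGA,Phenolic acids and their esters
25,12.74,635.0889,[M-H]-,C27H24O18,Tri-O-galloyl glucose 5,Tannins
26,13.19,635.0882,[M-H]-,C27H24O18,Tri-O-galloyl glucose 6,Tannins
27,14.45,331.0660,[M-H]-,C13H16O10,1-O-Galloyl glucose 2,Tannins
28,14.50,300.9987,[M-H]-,C14H6O8,Ellagic acid,Phenolic acids and their esters
29,15.52,787.0997,[M-H]-,C34H28O22,Tetra-O-galloyl glucose 1,Tannins
30,16.07,463.0870,[M-H]-,C21H20O12,Isoquercitrin,Flavonoids
31,16.13,483.0773,[M-H]-,C20H20O14,Di-O-galloyl glucose 4,Tannins
32,17.90,939.1112,[M-H]-,C41H32O26,Penta-O-galloyl glucose 1,Tannins
33,18.27,939.1105,[M-H]-,C41H32O26,Penta-O-galloyl glucose 2,Tannins
34,18.83,939.1107,[M-H]-,C41H32O26,Penta-O-galloyl glucose 3,Tannins
35,18.84,787.0998,[M-H]-,C34H28O22,Tetra-O-galloyl glucose 2,Tannins
36,27.48,277.1434,[M-H]-,C16H22O4,Dibutyl phthalate,Esters
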