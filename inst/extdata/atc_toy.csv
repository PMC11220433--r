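atc_code,label
H03AA01,Levothyroxine sodium
H03AA02,Liothyronine sodium
H03AA51,Levothyroxine and liothyronine
H03BB01,Carbimazole
H03BB02,Thiamazole
N06AX22,Agomelatine
N06AX21,Duloxetine
N06AB03,Fluoxetine
N06AB05,Paroxetine
N06AB06,Sertraline
N06AB10,Escitalopram
N05BA01,Diazepam
N05BA06,Lorazepam
N05BA12,Alprazolam
M03BX01,Baclofen
M03BX07,Tetrazepam
A10BX04,Exenatide
A10BA02,Metformin
A10AB01,Insulin human
M05BX03,Strontium ranelate
M05BA04,Alendronic acid
N02BE01,Paracetamol
M01AE01,Ibuprofen
N02BA01,Acetylsalicylic acid
N02AA01,Morphine
N02AX02,Tramadol
C07AB02,Metoprolol
C07AB07,Bisoprolol
C09AA02,Enalapril
C09AA05,Ramipril
C10AA01,Simvastatin
C10AA05,Atorvastatin
A02BC01,Omeprazole
A02BC05,Esomeprazole
R06AE07,Cetirizine
R06AX13,Loratadine
J01CA04,Amoxicillin
J01FA09,Clarithromycin
G03CA03,Estradiol
L04AX03,Methotrexate
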