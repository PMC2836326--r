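node,taxa,lower,upper
A,,419,472
B,,392,419
C,,345,392
D,,130,
E,,284,
F,,136,
G,,112,
H,,151,
I,,94,
J,,49,
K,,146,
L,,56,
M,,49,
N,,74,
O,,94,
P,,50,
Q,,98,
R,,32,
S,,85,95
T,,112,145
U,,100,120
V,,40,
W,,40,
X,,40,
Y,,7.6,
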