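spoken,symbol,mode
BEE,B,ALL
CEE,C,ALL
SEE,C,ALL
SEA,C,ALL
DEE,D,ALL
EFF,F,ALL
GEE,G,ALL
AITCH,H,ALL
HAITCH,H,ALL
JAY,J,ALL
KAY,K,ALL
ELL,L,ALL
EM,M,ALL
EN,N,ALL
OH,O,LETTERS
PEE,P,ALL
CUE,Q,ALL
QUEUE,Q,ALL
ARE,R,ALL
AR,R,ALL
ESS,S,ALL
TEE,T,ALL
TEA,T,ALL
YOU,U,ALL
VEE,V,ALL
EX,X,ALL
WHY,Y,ALL
ZEE,Z,ALL
ZED,Z,ALL
ZERO,0,ALL
OH,0,NUMBERS
O,0,NUMBERS
NOUGHT,0,ALL
ONE,1,ALL
WON,1,ALL
TWO,2,ALL
TOO,2,ALL
THREE,3,ALL
FOUR,4,ALL
FOR,4,ALL
FIVE,5,ALL
SIX,6,ALL
SEVEN,7,ALL
EIGHT,8,ALL
ATE,8,ALL
NINE,9,ALL
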