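# Median ddG (kcal/mol) for replacing the source amino acid (rows) by the
# destination amino acid (columns), aggregated over a FoldX mutational scan
# of 14,094 human proteins (7,214,402 sites x 19 substitutions).
# The W->V cell is printed "2..30" in the source table; transcribed as 2.30.
res,A,R,N,D,C,Q,E,G,H,I,L,K,M,F,P,S,T,W,Y,V
A,NA,-0.12,0.15,0.41,0.32,-0.07,0.09,0.72,0.25,0.28,-0.16,-0.15,-0.30,-0.12,2.43,0.22,0.53,0.04,-0.05,0.50
R,0.66,NA,0.58,0.97,0.82,0.33,0.63,1.16,0.66,0.60,0.17,0.13,0.08,0.24,2.88,0.74,0.94,0.43,0.33,0.93
N,0.35,-0.06,NA,0.34,0.42,0.08,0.25,0.67,0.34,0.40,-0.08,-0.08,-0.17,-0.07,2.47,0.39,0.66,0.16,0.01,0.69
D,0.32,0.12,0.17,NA,0.43,0.12,0.07,0.62,0.32,0.43,0.01,0.05,-0.07,0.00,1.81,0.42,0.65,0.23,0.09,0.69
C,0.20,0.45,0.36,0.89,NA,0.41,0.78,1.14,0.61,0.31,-0.14,0.22,-0.28,0.65,2.69,0.54,0.45,1.56,1.00,0.29
Q,0.38,-0.03,0.34,0.62,0.53,NA,0.23,0.91,0.37,0.20,-0.13,-0.06,-0.29,-0.05,2.57,0.49,0.63,0.11,0.05,0.58
E,0.29,0.02,0.34,0.43,0.53,0.03,NA,0.81,0.29,0.17,-0.18,-0.07,-0.27,-0.12,1.90,0.47,0.57,0.05,-0.03,0.49
G,2.12,1.91,2.10,2.37,2.36,2.31,2.47,NA,2.47,3.59,2.26,2.04,2.05,2.31,5.31,2.06,3.11,2.57,2.43,3.65
H,0.36,-0.11,0.23,0.66,0.42,0.04,0.32,0.92,NA,0.21,-0.33,-0.18,-0.50,-0.39,2.61,0.48,0.58,-0.11,-0.23,0.51
I,2.02,1.43,2.03,2.80,1.88,1.61,2.10,3.06,1.62,NA,0.06,1.20,0.05,0.83,3.95,2.49,1.73,1.54,1.23,0.81
L,1.67,1.13,1.73,2.34,1.81,1.35,1.70,2.61,1.46,0.78,NA,0.93,-0.01,0.44,3.97,2.07,1.91,0.98,0.77,1.48
K,0.50,0.05,0.46,0.79,0.71,0.21,0.46,1.02,0.51,0.21,0.01,NA,-0.09,0.07,2.52,0.62,0.80,0.26,0.16,0.75
M,1.24,0.82,1.27,1.68,1.49,0.95,1.16,2.04,1.16,0.76,0.19,0.65,NA,0.42,3.65,1.48,1.58,0.66,0.63,1.34
F,2.78,2.32,2.89,3.70,2.73,2.52,3.03,3.78,2.30,1.91,0.90,2.07,0.63,NA,4.59,3.13,2.95,0.94,0.50,2.42
P,0.90,0.63,0.90,0.80,1.00,0.70,0.58,1.02,0.77,0.94,0.68,0.65,0.64,0.64,NA,0.94,1.06,0.75,0.71,1.12
S,-0.01,-0.24,-0.01,0.12,0.09,-0.15,-0.04,0.29,0.10,0.26,-0.18,-0.24,-0.29,-0.18,1.90,NA,0.26,0.00,-0.11,0.48
T,0.15,-0.18,0.11,0.31,0.20,-0.08,0.06,0.55,0.11,-0.07,-0.28,-0.21,-0.37,-0.19,1.88,0.21,NA,0.03,-0.10,0.11
W,2.49,2.12,2.64,3.24,2.56,2.32,2.67,3.43,2.13,1.86,0.99,1.96,0.73,0.51,4.16,2.93,2.76,NA,0.82,2.30
Y,1.97,1.53,2.00,2.71,2.03,1.77,2.15,2.97,1.66,1.38,0.42,1.29,0.26,-0.06,4.12,2.46,2.27,0.45,NA,1.79
V,0.94,0.42,0.99,1.44,0.91,0.60,0.92,1.93,0.73,-0.27,-0.18,0.28,-0.17,0.17,2.87,1.37,0.71,0.61,0.38,NA
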