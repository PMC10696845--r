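icd10,phecode
N80.0,615
N80.1,615
N80.2,615
N80.3,615
N80.4,615
N80.5,615
N80.6,615
N80.8,615
N80.9,615
N92.0,625
N92.1,625
N92.4,625
D25.0,218
D25.1,218
D25.9,218
N83.0,620
N83.1,620
N83.2,620
I10,401
K21.0,530.11
K21.9,530.11
R10.1,785
R10.3,785
R10.4,785
N40,600
E78.0,272.11
E78.5,272.1
M79.7,710
F32.9,296.2
G43.9,340
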