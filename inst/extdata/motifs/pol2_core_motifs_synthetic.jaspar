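>SYN0001 Inr
A  [   2   2  94  25  48   2   2 ]
C  [  48  48   2  25   2  48  48 ]
G  [   2   2   2  25   2   2   2 ]
T  [  48  48   2  25  48  48  48 ]
>SYN0002 TATA-box
A  [   2  94   2  94  48  94  94  48 ]
C  [   2   2   2   2   2   2   2   2 ]
G  [   2   2   2   2   2   2   2  48 ]
T  [  94   2  94   2  48   2   2   2 ]
>SYN0003 MTE
A  [   2   2  94  48   2   2   2  94  94   2   2   2 ]
C  [  94  48   2   2  94  48  48   2   2  94   2  48 ]
G  [   2  48   2  48   2  48  48   2   2   2  94  48 ]
T  [   2   2   2   2   2   2   2   2   2   2   2   2 ]
>SYN0004 GC-Box
A  [   2   2   2   2   2   2   2   2   2 ]
C  [   2   2   2   2  94   2   2   2   2 ]
G  [  94  94  94  94   2  94  94  94  94 ]
T  [   2   2   2   2   2   2   2   2   2 ]
>SYN0005 CCAAT-Box
A  [  48  48   2   2  94  94   2   2  94 ]
C  [   2   2  94  94   2   2   2  48   2 ]
G  [  48  48   2   2   2   2   2  48   2 ]
T  [   2   2   2   2   2   2  94   2   2 ]
>SYN0006 DPE
A  [  48   2  48   2  33   2 ]
C  [   2   2   2  48  33   2 ]
G  [  48  94   2   2  33   2 ]
T  [   2   2  48  48   2  94 ]
>SYN0007 BREu
A  [   2   2  48   2   2   2   2 ]
C  [  48  48   2  94   2  94  94 ]
G  [  48  48  48   2  94   2   2 ]
T  [   2   2   2   2   2   2   2 ]
>SYN0008 BREd
A  [  48   2  33   2   2   2   2 ]
C  [   2   2   2   2   2   2   2 ]
G  [  48   2  33  48  48  48  48 ]
T  [   2  94  33  48  48  48  48 ]
>SYN0009 DCE-S-I
A  [   2   2   2   2 ]
C  [  94   2   2  94 ]
G  [   2   2   2   2 ]
T  [   2  94  94   2 ]
>SYN0010 DCE-S-II
A  [   2   2   2   2 ]
C  [  94   2   2   2 ]
G  [   2   2  94   2 ]
T  [   2  94   2  94 ]
>SYN0011 DCE-S-III
A  [  94   2   2 ]
C  [   2   2  94 ]
G  [   2  94   2 ]
T  [   2   2   2 ]
>SYN0012 XCPE1
A  [  33   2   2   2   2   2  48  94   2  48 ]
C  [   2  48   2  48   2   2   2   2  48  48 ]
G  [  33  48  94   2  94  94  48   2  48   2 ]
T  [  33   2   2  48   2   2   2   2   2   2 ]
>SYN0013 MED1
A  [   2   2   2   2   2   2 ]
C  [   2  94   2  94  94  48 ]
G  [  94   2   2   2   2  48 ]
T  [   2   2  94   2   2   2 ]
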