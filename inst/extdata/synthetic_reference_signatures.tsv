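channel	SynthRef1	SynthRef2	SynthRef3	SynthRef4	SynthRef5
A[C>A]A	0.0415422	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05
A[C>A]C	0.0443089	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05
A[C>A]G	0.0470756	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05
A[C>A]T	0.0498423	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05
C[C>A]A	0.052609	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05
C[C>A]C	0.0553757	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05
C[C>A]G	0.0581424	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05
C[C>A]T	0.0609091	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05
G[C>A]A	0.0636759	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05
G[C>A]C	0.0664426	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05
G[C>A]G	0.0692093	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05
G[C>A]T	0.071976	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05
T[C>A]A	0.0747427	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05
T[C>A]C	0.0775094	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05
T[C>A]G	0.0802761	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05
T[C>A]T	0.0830428	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05
A[C>G]A	4.15007e-05	0.0415422	4.15007e-05	4.15007e-05	4.15007e-05
A[C>G]C	4.15007e-05	0.0443089	4.15007e-05	4.15007e-05	4.15007e-05
A[C>G]G	4.15007e-05	0.0470756	4.15007e-05	4.15007e-05	4.15007e-05
A[C>G]T	4.15007e-05	0.0498423	4.15007e-05	4.15007e-05	4.15007e-05
C[C>G]A	4.15007e-05	0.052609	4.15007e-05	4.15007e-05	4.15007e-05
C[C>G]C	4.15007e-05	0.0553757	4.15007e-05	4.15007e-05	4.15007e-05
C[C>G]G	4.15007e-05	0.0581424	4.15007e-05	4.15007e-05	4.15007e-05
C[C>G]T	4.15007e-05	0.0609091	4.15007e-05	4.15007e-05	4.15007e-05
G[C>G]A	4.15007e-05	0.0636759	4.15007e-05	4.15007e-05	4.15007e-05
G[C>G]C	4.15007e-05	0.0664426	4.15007e-05	4.15007e-05	4.15007e-05
G[C>G]G	4.15007e-05	0.0692093	4.15007e-05	4.15007e-05	4.15007e-05
G[C>G]T	4.15007e-05	0.071976	4.15007e-05	4.15007e-05	4.15007e-05
T[C>G]A	4.15007e-05	0.0747427	4.15007e-05	4.15007e-05	4.15007e-05
T[C>G]C	4.15007e-05	0.0775094	4.15007e-05	4.15007e-05	4.15007e-05
T[C>G]G	4.15007e-05	0.0802761	4.15007e-05	4.15007e-05	4.15007e-05
T[C>G]T	4.15007e-05	0.0830428	4.15007e-05	4.15007e-05	4.15007e-05
A[C>T]A	4.15007e-05	4.15007e-05	0.0415422	4.15007e-05	4.15007e-05
A[C>T]C	4.15007e-05	4.15007e-05	0.0443089	4.15007e-05	4.15007e-05
A[C>T]G	4.15007e-05	4.15007e-05	0.0470756	4.15007e-05	4.15007e-05
A[C>T]T	4.15007e-05	4.15007e-05	0.0498423	4.15007e-05	4.15007e-05
C[C>T]A	4.15007e-05	4.15007e-05	0.052609	4.15007e-05	4.15007e-05
C[C>T]C	4.15007e-05	4.15007e-05	0.0553757	4.15007e-05	4.15007e-05
C[C>T]G	4.15007e-05	4.15007e-05	0.0581424	4.15007e-05	4.15007e-05
C[C>T]T	4.15007e-05	4.15007e-05	0.0609091	4.15007e-05	4.15007e-05
G[C>T]A	4.15007e-05	4.15007e-05	0.0636759	4.15007e-05	4.15007e-05
G[C>T]C	4.15007e-05	4.15007e-05	0.0664426	4.15007e-05	4.15007e-05
G[C>T]G	4.15007e-05	4.15007e-05	0.0692093	4.15007e-05	4.15007e-05
G[C>T]T	4.15007e-05	4.15007e-05	0.071976	4.15007e-05	4.15007e-05
T[C>T]A	4.15007e-05	4.15007e-05	0.0747427	4.15007e-05	4.15007e-05
T[C>T]C	4.15007e-05	4.15007e-05	0.0775094	4.15007e-05	4.15007e-05
T[C>T]G	4.15007e-05	4.15007e-05	0.0802761	4.15007e-05	4.15007e-05
T[C>T]T	4.15007e-05	4.15007e-05	0.0830428	4.15007e-05	4.15007e-05
A[T>A]A	4.15007e-05	4.15007e-05	4.15007e-05	0.0415422	4.15007e-05
A[T>A]C	4.15007e-05	4.15007e-05	4.15007e-05	0.0443089	4.15007e-05
A[T>A]G	4.15007e-05	4.15007e-05	4.15007e-05	0.0470756	4.15007e-05
A[T>A]T	4.15007e-05	4.15007e-05	4.15007e-05	0.0498423	4.15007e-05
C[T>A]A	4.15007e-05	4.15007e-05	4.15007e-05	0.052609	4.15007e-05
C[T>A]C	4.15007e-05	4.15007e-05	4.15007e-05	0.0553757	4.15007e-05
C[T>A]G	4.15007e-05	4.15007e-05	4.15007e-05	0.0581424	4.15007e-05
C[T>A]T	4.15007e-05	4.15007e-05	4.15007e-05	0.0609091	4.15007e-05
G[T>A]A	4.15007e-05	4.15007e-05	4.15007e-05	0.0636759	4.15007e-05
G[T>A]C	4.15007e-05	4.15007e-05	4.15007e-05	0.0664426	4.15007e-05
G[T>A]G	4.15007e-05	4.15007e-05	4.15007e-05	0.0692093	4.15007e-05
G[T>A]T	4.15007e-05	4.15007e-05	4.15007e-05	0.071976	4.15007e-05
T[T>A]A	4.15007e-05	4.15007e-05	4.15007e-05	0.0747427	4.15007e-05
T[T>A]C	4.15007e-05	4.15007e-05	4.15007e-05	0.0775094	4.15007e-05
T[T>A]G	4.15007e-05	4.15007e-05	4.15007e-05	0.0802761	4.15007e-05
T[T>A]T	4.15007e-05	4.15007e-05	4.15007e-05	0.0830428	4.15007e-05
A[T>C]A	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05	0.0415422
A[T>C]C	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05	0.0443089
A[T>C]G	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05	0.0470756
A[T>C]T	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05	0.0498423
C[T>C]A	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05	0.052609
C[T>C]C	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05	0.0553757
C[T>C]G	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05	0.0581424
C[T>C]T	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05	0.0609091
G[T>C]A	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05	0.0636759
G[T>C]C	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05	0.0664426
G[T>C]G	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05	0.0692093
G[T>C]T	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05	0.071976
T[T>C]A	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05	0.0747427
T[T>C]C	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05	0.0775094
T[T>C]G	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05	0.0802761
T[T>C]T	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05	0.0830428
A[T>G]A	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05
A[T>G]C	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05
A[T>G]G	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05
A[T>G]T	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05
C[T>G]A	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05
C[T>G]C	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05
C[T>G]G	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05
C[T>G]T	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05
G[T>G]A	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05
G[T>G]C	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05
G[T>G]G	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05
G[T>G]T	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05
T[T>G]A	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05
T[T>G]C	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05
T[T>G]G	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05
T[T>G]T	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05	4.15007e-05
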