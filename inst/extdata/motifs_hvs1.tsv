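label	parent	motif
rCRS		
L0a	rCRS	G16129A C16148T T16172C C16187T C16188G T16189C C16223T A16230G T16311C C16320T
L1b	rCRS	T16126C C16187T T16189C C16223T C16264T C16270T C16278T T16311C
L1c	rCRS	G16129A C16187T T16189C C16223T C16278T C16294T T16311C C16360T
L2	rCRS	C16223T C16278T
L2a	L2	C16223T C16278T C16294T
L2a1	L2a	C16223T C16278T C16294T A16309G
L2b	L2	C16114A G16129A G16213A C16223T C16278T C16355T T16362C
L2c	L2	C16223T C16264T C16278T
L3	rCRS	C16223T
L3b	L3	T16124C C16223T C16278T T16362C
L3d	L3	T16124C C16223T
L3e	L3	C16223T C16327T
L3f	L3	T16209C C16223T T16311C
L3h	L3	G16129A C16223T C16256A
L4b	rCRS	C16223T C16355T T16362C
L5	rCRS	C16148T A16166G C16187T T16189C C16223T C16278T T16311C C16320T
U6	rCRS	T16172C A16219G
U6a	U6	T16172C A16219G C16278T
U2	rCRS	A16051G G16129C
J	rCRS	C16069T T16126C
T	rCRS	T16126C C16294T
K	rCRS	T16224C T16311C
H2a2b1	rCRS	A16235G C16291T A16293G
A2	rCRS	C16111T C16223T C16290T G16319A T16362C
B4	rCRS	T16189C T16217C
D4	rCRS	C16223T T16362C
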