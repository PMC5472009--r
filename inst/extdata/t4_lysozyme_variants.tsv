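variant	mutant_pdb	effect
G77A	1L23	Neutral
A82P	1L24	Neutral
A93T	129L	Neutral
T151S	130L	Neutral
T26S	131L	Neutral
V149M	1CV6	Neutral
V87M	1CU3	Destabilizing
S38N	1L61	Neutral
T109N	1L59	Neutral
T109D	1L62	Neutral
N116D	1L57	Neutral
D92N	1L55	Destabilizing
S38D	1L19	Neutral
N144D	1L20	Neutral
M106I	1P46	Neutral
M120Y	1P6Y	Neutral
V149I	1G0Q	Neutral
T152V	1G0L	Neutral
V149S	1G06	Destabilizing
V149C	1G07	Destabilizing
V149G	1G0P	Destabilizing
E108V	1QUG	Neutral
L99G	1QUD	Destabilizing
S117F	1TLA	Neutral
M106L	234L	Neutral
M120L	233L	Neutral
M106K	231L	Destabilizing
M120K	232L	Destabilizing
I3V	1L17	Neutral
I3Y	1L18	Destabilizing
M102K	1L54	Destabilizing
T157I	1L10	Destabilizing
G156D	1L16	Destabilizing
R96H	1L34	Destabilizing
I3P	1L97	Destabilizing
R96N	3CDT	Destabilizing
R96D	3C8Q	Destabilizing
R96W	3FI5	Destabilizing
R96Y	3C80	Destabilizing
M102L	1L77	Destabilizing
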