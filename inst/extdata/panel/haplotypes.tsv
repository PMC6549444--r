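segment	label	strain	edits	indels
COIB	COI-CSa1	corn		
COIB	COI-CSa2	corn	1164=A	
COIB	COI-RSa1	rice	1164=T,1287=A,1197=G,1216=T,1125=T,1176=T,1182=T	
COIB	COI-RSa2	rice	1164=T,1287=A,1197=G,1216=T,1176=T,1182=T	
COIB	COI-RSa3	rice	1164=T,1287=A,1197=G,1216=T,1125=T,1182=T	
COIB	COI-RSa4	rice	1164=T,1287=A,1197=G,1216=T,1125=T,1176=T	
TpiE4	TpiCa1	corn		
TpiE4	TpiCa2	corn	192=T,198=T	
TpiE4	TpiRa1	rice	129=C,144=G,168=T,180=C,183=T	
TpiI4	TpiI4Ca1a	na		
TpiI4	TpiI4Ca1b	na		ins:100:TpiI4Ca1b_ins
TpiI4	TpiI4Ca2a	na	20=C,45=A,75=T,105=A,140=T	
TpiI4	TpiI4Ca2b	na	20=C,45=A,75=T,105=A,140=T,60=A,90=A	
TpiI4	TpiI4Ca2c	na	20=C,45=A,75=T,105=A,140=T,60=A,90=A,25=C,50=G,115=T,155=T	
TpiI4	TpiI4Ra1a	na	15=T,30=G,35=G,40=G,55=A,70=T,95=G,110=A,125=A,150=C,160=C,165=A	
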