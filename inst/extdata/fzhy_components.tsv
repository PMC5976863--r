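herb	component
S. miltiorrhiza	Salvianolic acid A
S. miltiorrhiza	baicalin
S. miltiorrhiza	dihydrotanshinone I
S. miltiorrhiza	rosmarinic acid
S. miltiorrhiza	ursolic acid
S. miltiorrhiza	danshensu
S. miltiorrhiza	ferulic acid
S. miltiorrhiza	magnesium lithospermate B
S. miltiorrhiza	protocatechuic aldehyde
S. miltiorrhiza	tanshinol
S. miltiorrhiza	rutin
S. miltiorrhiza	tanshinone II-A
S. miltiorrhiza	salvianolic acid B
S. miltiorrhiza	β-sitosterol
C. sinensis	Histidine
C. sinensis	ergosterol
C. sinensis	valine
C. sinensis	adenosine
C. sinensis	ascorbic acid
C. sinensis	vitamin B12
C. sinensis	vitamin A
C. sinensis	nicotinic acid
C. sinensis	glycine
C. sinensis	cordycepin
C. sinensis	linoleic acid
C. sinensis	β-sitosterol
S. chinensis	β-caryophyllene
S. chinensis	β-elemene
S. chinensis	schizandrin
S. chinensis	vitamin k1
S. chinensis	schisandrol B
S. chinensis	schisantherin A
S. chinensis	schisandrin B
S. chinensis	β-sitosterol
G. pentaphyllum	Ginsenoside-rb1
G. pentaphyllum	rutin
G. pentaphyllum	ginsenoside-rb2
G. pentaphyllum	gypenoside XLIX
G. pentaphyllum	gipsoside
G. pentaphyllum	gypenoside A
G. pentaphyllum	β-sitosterol
S. Persicae	Chlorogenic acid
S. Persicae	amygdalin
S. Persicae	(+)-catechin
S. Persicae	β-sitosterol
P. Pini	Kaempferol
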