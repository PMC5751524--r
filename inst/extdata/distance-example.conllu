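# sent_id = f2.s0
1	The	_	_	_	_	2	det	_	_
2	findings	_	_	_	_	3	nsubj	_	_
3	suggest	_	_	_	_	0	root	_	_
4	that	_	_	_	_	11	mark	_	_
5	the	_	_	_	_	6	det	_	_
6	dosage	_	_	_	_	11	nsubj	_	_
7	of	_	_	_	_	8	case	_	_
8	S-ketamine	_	_	_	_	6	nmod	_	_
9	should	_	_	_	_	11	aux	_	_
10	be	_	_	_	_	11	aux	_	_
11	reduced	_	_	_	_	3	ccomp	_	_
12	in	_	_	_	_	13	case	_	_
13	patients	_	_	_	_	11	obl	_	_
14	receiving	_	_	_	_	13	acl	_	_
15	ticlopidine	_	_	_	_	14	obj	_	_

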