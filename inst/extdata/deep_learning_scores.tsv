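method	experiment	precision	recall	fmeasure	accuracy
BiOnt	original	0.8140	0.3070	0.4459	0.4821
BiOnt	task1-train+original-test	0.7000	0.9825	0.8175	0.7024
BiOnt	task1-train+consensus-task2-test	0.6810	0.9670	0.7992	0.6726
BiOnt	task1-train+expert-task2-test	0.8142	0.9721	0.8861	0.7989
BiOnt	consensus-task2-train+original-test	0.6880	0.8509	0.7608	0.6369
BiOnt	expert-task2-train+original-test	0.6894	0.9737	0.8072	0.6845
BioBERT	original	0.8542	0.3445	0.4910	0.5143
BioBERT	task1-train+original-test	0.6744	0.9856	0.8000	0.6775
BioBERT	task1-train+consensus-task2-test	0.6700	0.9763	0.7946	0.6680
BioBERT	task1-train+expert-task2-test	0.8103	0.9906	0.8915	0.8096
BioBERT	consensus-task2-train+original-test	0.7315	0.9160	0.8134	0.7143
BioBERT	expert-task2-train+original-test	0.7857	0.8319	0.8082	0.7314
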