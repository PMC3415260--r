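Books	ebook
Books	isbn
Books	paperback
Books	hardcover
Books	bestseller
Books	copyright
Education	thesis
Education	assignment
Education	homework
Education	syllabus
Education	coursework
Education	dissertation
Retail	tim hortons
Retail	walmart
Retail	coupon
Retail	clearance
Retail	advertisement
Retail	catalog
Periodical	magazine
Periodical	article
Periodical	newsletter
Periodical	editorial
Periodical	columnist
Fictional	harry porter
Fictional	bart simpson
Fictional	darth vader
Fictional	sherlock holmes
Fictional	paris hilton
Fictional	hermione granger
Politics	nicolas sarkozy
Politics	george bush
Politics	barack obama
Politics	stephen harper
Politics	tony blair
Politics	angela merkel
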