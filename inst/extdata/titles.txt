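The Abominable Snowman
Iron Crypt of the Heretics
The Haunted Lighthouse
New York, New York
The Winner Takes It All
Quick Recipe And Meal Ideas
36 Christmas Carols & Songs
Pride and Prejudice
Wuthering Heights
Great Expectations
A Tale of Two Cities
Moby Dick
Treasure Island
The Call of the Wild
Twenty Thousand Leagues Under the Sea
Around the World in Eighty Days
The Count of Monte Cristo
The Three Musketeers
Anne of Green Gables
Little Women
The Secret Garden
The Wind in the Willows
Gulliver's Travels
Robinson Crusoe
The Picture of Dorian Gray
The Importance of Being Earnest
Heart of Darkness
The Time Machine
The War of the Worlds
The Invisible Man
Dracula
Frankenstein
The Strange Case of Dr Jekyll and Mr Hyde
Sense and Sensibility
Emma
Persuasion
Jane Eyre
David Copperfield
Oliver Twist
Bleak House
Hard Times
The Adventures of Tom Sawyer
The Prince and the Pauper
A Connecticut Yankee
The Jungle Book
Kim
Captains Courageous
White Fang
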